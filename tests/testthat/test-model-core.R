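test_that("reaction formula grammar round-trips", {
  cases <- c("glc[c] -> 2 pyr[c] + 2 atp[c]",
             "A[c] + 2 B[c] -> C[e]",
             "A[e] <=> A[c]",
             "ser[e] ->",
             "-> thf[c]",
             "0.5 x[c] + 1.25 y[c] -> z[c]")
  for (f in cases) {
    p <- parse_reaction_formula(f)
    f2 <- format_reaction_formula(p$stoichiometry, p$reversible)
    p2 <- parse_reaction_formula(f2)
    expect_equal(p2$stoichiometry[order(names(p2$stoichiometry))],
                 p$stoichiometry[order(names(p$stoichiometry))])
    expect_identical(p2$reversible, p$reversible)
  }
  expect_error(parse_reaction_formula("A[c] + B[c]"), "arrow")
  expect_error(parse_reaction_formula(" -> "), "empty")
})

test_that("model assembly infers kinds, compartments and metabolites", {
  m <- chain_model()
  expect_equal(n_metabolites(m), 2)
  expect_equal(n_reactions(m), 3)
  expect_equal(reactions(m)$kind, c("exchange", "internal", "exchange"))
  m2 <- toy_microbe()
  expect_true(all(metabolites(m2)$compartment %in% m2$compartments))
  tr <- reactions(m2)$kind[reactions(m2)$id == "T_glc"]
  expect_identical(tr, "transport")
})

test_that("stoichiometric matrix matches declared coefficients", {
  m <- chain_model()
  S <- stoichiometric_matrix(m, sparse = FALSE)
  expect_equal(dim(S), c(2, 3))
  expect_equal(S["A[c]", "EX_A"], -1)
  expect_equal(S["A[c]", "R1"], -1)
  expect_equal(S["B[c]", "R1"], 1)
  empty <- metabolic_model(tibble::tibble(id = character(0),
                                          stoichiometry = list()),
                           objective = stats::setNames(numeric(0),
                                                       character(0)))
  expect_equal(dim(stoichiometric_matrix(empty)), c(0, 0))
})

test_that("S construction is order independent and matches independent assembly", {
  m <- random_toy_lp_model(7)
  S <- stoichiometric_matrix(m, sparse = FALSE)
  # independent assembly: metabolite-wise accumulation
  S2 <- matrix(0, n_metabolites(m), n_reactions(m),
               dimnames = list(metabolites(m)$id, reactions(m)$id))
  for (mi in metabolites(m)$id) {
    for (k in seq_len(n_reactions(m))) {
      st <- reactions(m)$stoichiometry[[k]]
      if (mi %in% names(st)) S2[mi, reactions(m)$id[k]] <- st[[mi]]
    }
  }
  expect_equal(S, S2)
  perm <- m
  ord <- rev(seq_len(n_reactions(m)))
  perm$reactions <- perm$reactions[ord, ]
  Sp <- stoichiometric_matrix(perm, sparse = FALSE)
  expect_equal(Sp[, colnames(S)], S)
})

test_that("validate_model reports violations without throwing", {
  m <- chain_model()
  expect_true(is_clean(validate_model(m)))
  bad <- m
  bad$reactions$lb[2] <- 5
  bad$reactions$ub[2] <- 1
  rep <- validate_model(bad)
  expect_identical(rep$bound_violations, "R1")
  dup <- m
  dup$reactions <- dplyr::bind_rows(dup$reactions, dup$reactions[2, ])
  expect_true("R1" %in% validate_model(dup)$duplicate_ids)
  # demand with uptake allowed is structurally invalid but must not throw
  dm <- m
  dm$reactions$kind[3] <- "demand"
  dm$reactions$lb[3] <- -5
  expect_no_error(rep2 <- validate_model(dm))
  expect_true("EX_B" %in% rep2$unbalanced_reactions)
})

test_that("exchange normalisation flips importer-style exchanges", {
  raw <- metabolic_model(dplyr::bind_rows(
    rxn_row("EX_A", "-> A[c]", 0, 10),   # importer style: +1 coefficient
    rxn_row("R1", "A[c] -> B[c]", 0, 1000),
    rxn_row("EX_B", "B[c] ->", 0, 1000)),
    objective = c(EX_B = 1))
  nm <- normalize_exchanges(raw)
  st <- nm$reactions$stoichiometry[[1]]
  expect_equal(unname(st), -1)
  expect_equal(nm$reactions$lb[1], -10)
  expect_equal(nm$reactions$ub[1], 0)
  # flux semantics preserved: can still feed 10 units of A
  expect_equal(fba(nm)$objective, 10)
})
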