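test_that("zscore_to_pvalue is the normal survival function", {
  expect_equal(zscore_to_pvalue(0), 0.5)
  expect_equal(zscore_to_pvalue(qnorm(0.95)), 0.05)
  expect_true(zscore_to_pvalue(-3) > 0.99)
})

test_that("fisher_right_tail matches exhaustive enumeration on random instances", {
  set.seed(11)
  for (i in 1:500) {
    N <- sample(4:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(
      fisher_right_tail(k, K, n, N),
      hyper_tail_oracle(k, K, n, N),
      tolerance = 1e-13
    )
  }
  expect_error(fisher_right_tail(5, 4, 10, 20), "inconsistent")
  expect_error(fisher_right_tail(1, 30, 10, 20), "inconsistent")
})

test_that("fisher_right_tail agrees with fisher.test's right tail", {
  skip_if_not_installed("stats")
  for (case in list(c(4, 5, 4, 17), c(3, 8, 6, 30), c(1, 2, 5, 12))) {
    k <- case[1]; K <- case[2]; n <- case[3]; N <- case[4]
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
    expect_equal(
      fisher_right_tail(k, K, n, N),
      stats::fisher.test(tab, alternative = "greater")$p.value,
      tolerance = 1e-12
    )
  }
})

test_that("run_ora applies the DA threshold and min-hits rule", {
  bg <- sprintf("m%02d", 1:20)
  profile <- tibble::tibble(
    metabolite = bg,
    z = c(rep(3, 4), rep(0, 16)) # exactly four DA metabolites
  )
  sets <- make_sets(
    hitset = bg[1:5], # 4 DA of 5 members -> testable
    twohits = c(bg[1:2], bg[10:12]), # 2 DA -> below min_hits
    coldset = bg[10:15]
  )
  res <- run_ora(profile, sets, bg)
  hit <- res[res$pathway_id == "hitset", ]
  expect_true(hit$testable)
  expect_equal(hit$n_hits, 4L)
  expect_equal(hit$p_value, hyper_tail_oracle(4, 5, 4, 20), tolerance = 1e-13)
  expect_false(res$testable[res$pathway_id == "twohits"])
  expect_true(is.na(res$p_value[res$pathway_id == "twohits"]))
  expect_false(res$testable[res$pathway_id == "coldset"])
})

test_that("ORA signed default ignores decreases; abs mode counts them", {
  bg <- sprintf("m%02d", 1:20)
  profile <- tibble::tibble(metabolite = bg, z = c(rep(-3, 4), rep(0, 16)))
  sets <- make_sets(downset = bg[1:5])
  signed <- run_ora(profile, sets, bg)
  expect_false(signed$testable[[1]]) # negative z never DA under the survival function
  absres <- run_ora(profile, sets, bg, da_stat = "abs")
  expect_true(absres$testable[[1]])
  expect_equal(absres$n_hits[[1]], 4L)
})

test_that("run_ora rejects bad inputs", {
  profile <- tibble::tibble(metabolite = "x", z = 1)
  sets <- make_sets(A = "x")
  expect_error(run_ora(profile, sets, character()), "empty background")
  expect_error(run_ora(profile, sets, background = "y"), "outside the background")
})

test_that("enrichment_score matches step-by-step enumeration on short lists", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    ids <- sprintf("m%d", 1:n)
    scores <- sort(round(rnorm(n), 3), decreasing = TRUE)
    names(scores) <- ids
    k <- sample(1:(n - 1), 1)
    members <- sample(ids, k)
    ranked <- tibble::tibble(metabolite = ids, score = unname(scores))
    got <- enrichment_score(ranked, members)
    oracle <- es_oracle(scores, members)
    if (es_sign_tied(oracle)) {
      expect_equal(abs(got$es), abs(c(oracle)), tolerance = 1e-12)
    } else {
      expect_equal(got$es, c(oracle), tolerance = 1e-12)
    }
    expect_gte(got$es, -1)
    expect_lte(got$es, 1)
  }
})

test_that("a single-top-member set scores es = 1 exactly", {
  ranked <- tibble::tibble(
    metabolite = sprintf("m%d", 1:10),
    score = seq(5, 0.5, by = -0.5)
  )
  expect_identical(enrichment_score(ranked, "m1")$es, 1)
  expect_equal(enrichment_score(ranked, "m1")$position, 1L)
})

test_that("enrichment_score rejects degenerate sets", {
  ranked <- tibble::tibble(metabolite = c("a", "b"), score = c(2, 1))
  expect_error(enrichment_score(ranked, "zzz"), "no member")
  expect_error(enrichment_score(ranked, c("a", "b")), "covers the whole")
})

test_that("rank_metabolites orders by mode with stable ties", {
  profile <- tibble::tibble(metabolite = c("a", "b", "c"), z = c(-5, 2, 2))
  signed <- rank_metabolites(profile, "signed")
  expect_equal(signed$metabolite, c("b", "c", "a"))
  absr <- rank_metabolites(profile, "absolute")
  expect_equal(absr$metabolite, c("a", "b", "c"))
  expect_error(
    rank_metabolites(tibble::tibble(metabolite = c("a", "a"), z = 1:2)),
    "unique"
  )
})

test_that("run_gsea is seed-deterministic and flags non-testable sets", {
  set.seed(5)
  profile <- tibble::tibble(metabolite = sprintf("m%02d", 1:30), z = rnorm(30))
  sets <- make_sets(
    inlist = sprintf("m%02d", 1:6),
    absent = c("zz1", "zz2"),
    everything = sprintf("m%02d", 1:30)
  )
  a <- run_gsea(profile, sets, mode = "signed", n_perm = 99, seed = 42)
  b <- run_gsea(profile, sets, mode = "signed", n_perm = 99, seed = 42)
  expect_equal(a$p_value, b$p_value)
  expect_false(a$testable[a$pathway_id == "absent"])
  expect_false(a$testable[a$pathway_id == "everything"])
  expect_true(a$testable[a$pathway_id == "inlist"])
  p <- a$p_value[a$pathway_id == "inlist"]
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
})

test_that("a set of the top metabolites is significant under GSEA", {
  set.seed(8)
  z <- sort(rnorm(100), decreasing = TRUE)
  profile <- tibble::tibble(metabolite = sprintf("m%03d", 1:100), z = z)
  sets <- make_sets(top = sprintf("m%03d", 1:3))
  res <- run_gsea(profile, sets, mode = "signed", n_perm = 999, seed = 1)
  expect_lte(res$p_value, 0.05)
})

test_that("GSEA enrichment scores agree with fgsea on a shared input", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  z <- rnorm(50)
  names(z) <- sprintf("m%02d", 1:50)
  pw <- list(A = sprintf("m%02d", c(1, 5, 9, 22, 40)), B = sprintf("m%02d", 30:38))
  profile <- tibble::tibble(metabolite = names(z), z = unname(z))
  sets <- make_sets(A = pw$A, B = pw$B)
  mine <- run_gsea(profile, sets, mode = "signed", n_perm = 99, seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(pw, sort(z, decreasing = TRUE), scoreType = "std", nproc = 1)
  )
  for (p in c("A", "B")) {
    expect_equal(
      mine$es[mine$pathway_id == p],
      ref$ES[ref$pathway == p],
      tolerance = 1e-6
    )
  }
})
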