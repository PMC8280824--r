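test_that("identical counts give a null test result", {
  fit <- betabin_test(c(10, 12), c(50, 60), c(10, 12), c(50, 60))
  expect_equal(fit$statistic, 0, tolerance = 1e-6)
  expect_equal(fit$p.value, 1, tolerance = 1e-6)
  expect_equal(fit$delta_psi, 0)

  single <- betabin_test(10, 20, 10, 20)
  expect_equal(single$delta_psi, 0)
})

test_that("rho = 0 reduces exactly to the binomial likelihood-ratio test", {
  cases <- list(
    list(rc = c(10, 12, 8), nc = c(100, 110, 90),
         rt = c(20, 15, 22), nt = c(95, 105, 100)),
    list(rc = c(0, 1), nc = c(30, 25), rt = c(5, 9), nt = c(28, 33)),
    list(rc = 50, nc = 100, rt = 10, nt = 100)
  )
  for (cs in cases) {
    fit <- betabin_test(cs$rc, cs$nc, cs$rt, cs$nt, rho = 0)
    expect_equal(fit$p.value,
                 oracle_binom_lrt_p(cs$rc, cs$nc, cs$rt, cs$nt),
                 tolerance = 1e-10)
    expect_equal(fit$method, "binomial")
  }
})

test_that("all-zero totals yield an uninformative result", {
  fit <- betabin_test(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(fit$p.value, 1)
  expect_true(is.na(fit$delta_psi))
})

test_that("per-pair estimated rho is conservative but detects clean shifts", {
  # binomial data: the alternative-model rho sits near its lower bound,
  # while the null model may absorb part of the shift as overdispersion,
  # so the free-rho test is never more significant than the binomial one
  fit <- betabin_test(c(10, 11, 9), c(100, 100, 100),
                      c(30, 29, 31), c(100, 100, 100))
  expect_lt(fit$estimate[["rho"]], 0.01)
  oracle <- oracle_binom_lrt_p(c(10, 11, 9), c(100, 100, 100),
                               c(30, 29, 31), c(100, 100, 100))
  expect_gte(fit$p.value, oracle)
  expect_lt(fit$p.value, 0.01)
})

test_that("tidy and glance return one-row summaries", {
  fit <- betabin_test(c(5, 6), c(40, 45), c(20, 18), c(42, 38))
  td <- tidy(fit)
  expect_equal(nrow(td), 1L)
  expect_true(all(c("mu_control", "mu_treat", "rho", "delta_psi",
                    "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$p.value, fit$p.value)
})

test_that("estimate_common_rho recovers the simulated overdispersion", {
  set.seed(202)
  sim_groups <- function(rho, n_groups = 400) {
    purrr::map_dfr(seq_len(n_groups), function(g) {
      mu <- runif(1, 0.05, 0.6)
      n <- rnbinom(3, mu = 70, size = 8)
      p <- if (rho > 0) rbeta(3, mu * (1 - rho) / rho,
                              (1 - mu) * (1 - rho) / rho) else mu
      tibble::tibble(g = g, n = n, r = rbinom(3, n, p))
    })
  }
  for (rho in c(0, 0.05, 0.15)) {
    d <- sim_groups(rho)
    est <- estimate_common_rho(d$r, d$n, d$g)
    expect_lt(abs(est - rho), 0.02)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # independent step-up oracle on a random vector
  set.seed(7)
  p <- runif(25)
  o <- order(p)
  stepped <- p[o] * length(p) / seq_along(p)
  stepped <- rev(cummin(rev(stepped)))
  want <- numeric(length(p)); want[o] <- pmin(stepped, 1)
  expect_equal(adjust_bh(p), want)

  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH never decreases p-values and preserves their order", {
  set.seed(8)
  p <- runif(40)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("Mann-Whitney exact path equals full enumeration (n <= 8)", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p.value, 1 / 3,
               tolerance = 1e-12)
  set.seed(91)
  for (sizes in list(c(2, 3), c(3, 3), c(4, 4), c(3, 5), c(2, 6))) {
    for (rep in 1:5) {
      vals <- sample(1000, sum(sizes))  # distinct -> no ties
      x <- vals[seq_len(sizes[1])]
      y <- vals[-seq_len(sizes[1])]
      got <- mann_whitney(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p.value, oracle_mw_p(x, y), tolerance = 1e-9)
    }
  }
})

test_that("Mann-Whitney degenerate and approximate paths behave", {
  same <- mann_whitney(c(2, 2, 2), c(2, 2))
  expect_equal(same$p.value, 1)
  expect_equal(same$U, 3)

  set.seed(92)
  x <- rnorm(6); y <- rnorm(6)
  exact <- mann_whitney(x, y)$p.value
  approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(exact - approx), 0.02)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("subtype summary reports fractions, shifts and the A-vs-G test", {
  results <- tibble::tibble(
    intron_id = sprintf("i%02d", 1:20),
    delta_psi = c(rep(0.4, 10), rep(0.05, 10)),
    statistic = 1, p = 0.01, p_adj = c(rep(0.01, 9), 0.5,
                                       rep(0.01, 2), rep(0.5, 8)),
    affected_ir = c(rep(TRUE, 9), FALSE, rep(TRUE, 2), rep(FALSE, 8)),
    affected_strict = c(rep(TRUE, 9), FALSE, rep(FALSE, 10)),
    method = "beta-binomial"
  )
  classifications <- tibble::tibble(
    intron_id = sprintf("i%02d", 1:20),
    spliceosome_type = "minor",
    subtype = c(rep("A", 10), rep("G", 10))
  )
  s <- summarize_by_subtype(results, classifications, affected = "ir")
  expect_equal(s$fraction_affected[s$subtype == "A"], 0.9)
  expect_equal(s$fraction_affected[s$subtype == "G"], 0.2)
  expect_equal(s$mean_delta_psi, c(0.4, 0.05))
  expect_lt(s$mw_p[1], 0.01)

  strict <- summarize_by_subtype(results, classifications,
                                 affected = "strict")
  expect_equal(strict$fraction_affected, c(0.9, 0))
})

test_that("equal shift distributions give a flat subtype comparison", {
  results <- tibble::tibble(
    intron_id = sprintf("i%02d", 1:10), delta_psi = 0, statistic = 0,
    p = 1, p_adj = 1, affected_ir = FALSE, affected_strict = FALSE,
    method = "beta-binomial"
  )
  classifications <- tibble::tibble(
    intron_id = sprintf("i%02d", 1:10), spliceosome_type = "minor",
    subtype = rep(c("A", "G"), 5)
  )
  s <- summarize_by_subtype(results, classifications)
  expect_equal(s$mean_delta_psi, c(0, 0))
  expect_equal(s$mw_p, c(1, 1))
})

test_that("cryptic activation union feeds the combined affected fraction", {
  results <- tibble::tibble(
    intron_id = c("i1", "i2"), delta_psi = 0, statistic = 0, p = 1,
    p_adj = 1, affected_ir = FALSE, affected_strict = FALSE,
    method = "beta-binomial"
  )
  classifications <- tibble::tibble(
    intron_id = c("i1", "i2"), spliceosome_type = "minor",
    subtype = c("A", "A")
  )
  cryptic <- tibble::tibble(intron_id = "i1", activated = TRUE)
  s <- summarize_by_subtype(results, classifications,
                            affected = "ir_or_cryptic", cryptic = cryptic)
  expect_equal(s$fraction_affected[s$subtype == "A"], 0.5)
})

# Brute-force average-linkage agglomeration for the clustering oracle.
oracle_average_linkage <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[i]], clusters[[j]])),
           height = best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  merges
}

test_that("identical retention profiles merge first", {
  m <- rbind(a = c(0.1, 0.1), b = c(0.1, 0.1), c = c(0.9, 0.9))
  cl <- cluster_retention(m)
  first <- cl$tree$merge[1, ]
  expect_setequal(-first, c(1, 2))
})

test_that("clustering matches brute-force average linkage on 4 points", {
  set.seed(17)
  for (rep in 1:5) {
    m <- matrix(runif(12), nrow = 4,
                dimnames = list(paste0("r", 1:4), NULL))
    cl <- cluster_retention(m)
    want <- oracle_average_linkage(m)
    got_heights <- cl$tree$height
    expect_equal(got_heights, vapply(want, `[[`, 0, "height"),
                 tolerance = 1e-9)
    # members of each merge agree
    members_of <- function(tree, step) {
      grab <- function(idx) {
        if (idx < 0) return(-idx)
        members_of(tree, idx)
      }
      sort(unlist(lapply(tree$merge[step, ], grab)))
    }
    for (s in seq_along(want)) {
      expect_equal(members_of(cl$tree, s), want[[s]]$members)
    }
  }
})

test_that("clustering is invariant to row permutation", {
  set.seed(18)
  m <- matrix(runif(20), nrow = 5,
              dimnames = list(paste0("r", 1:5), NULL))
  perm <- sample(5)
  a <- cluster_retention(m)
  b <- cluster_retention(m[perm, ])
  expect_equal(a$tree$height, b$tree$height, tolerance = 1e-12)
  expect_equal(a$leaf_order, b$leaf_order)
})

test_that("rows with missing psi are dropped with a warning", {
  m <- rbind(a = c(0.1, NA), b = c(0.2, 0.3), c = c(0.8, 0.9))
  expect_warning(cl <- cluster_retention(m), "missing")
  expect_equal(cl$dropped, "a")
  m1 <- rbind(a = c(0.1, NA), b = c(0.2, 0.3))
  expect_warning(trivial <- cluster_retention(m1), "missing")
  expect_null(trivial$tree)
  expect_equal(trivial$leaf_order, "b")
})

cryptic_fixture <- function(alt_ctl, alt_trt, canon_ctl, canon_trt) {
  junctions <- dplyr::bind_rows(
    tibble::tibble(contig = "chr1", start = 100L, end = 200L,
                   sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                   count = c(canon_ctl, canon_trt)),
    tibble::tibble(contig = "chr1", start = 130L, end = 200L,
                   sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                   count = c(alt_ctl, alt_trt))
  )
  design <- tibble::tibble(sample_id = c("c1", "c2", "c3",
                                         "t1", "t2", "t3"),
                           condition = rep(c("control", "treatment"),
                                           each = 3))
  introns <- intron_row("chr1", 100L, 200L)
  list(junctions = junctions, design = design, introns = introns)
}

test_that("a strong alternative-junction shift is called activated", {
  fx <- cryptic_fixture(alt_ctl = c(0, 0, 0), alt_trt = c(14, 13, 13),
                        canon_ctl = c(17, 17, 16), canon_trt = c(4, 3, 3))
  ev <- detect_cryptic(fx$junctions, fx$introns, fx$design)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$alt_start, 130L)
  expect_true(ev$activated)
  expect_gt(ev$delta_psi_alt, 0.1)
})

test_that("unchanged alternative usage is not called activated", {
  fx <- cryptic_fixture(alt_ctl = c(5, 5, 5), alt_trt = c(5, 5, 5),
                        canon_ctl = c(45, 45, 45),
                        canon_trt = c(45, 45, 45))
  ev <- detect_cryptic(fx$junctions, fx$introns, fx$design)
  expect_equal(nrow(ev), 1L)
  expect_false(ev$activated)
})

test_that("candidate junctions must sit near a canonical boundary", {
  junctions <- tibble::tibble(
    contig = "chr1", start = 400L, end = 500L,
    sample_id = c("c1", "t1"), count = c(10L, 10L)
  )
  design <- tibble::tibble(sample_id = c("c1", "t1"),
                           condition = c("control", "treatment"))
  introns <- intron_row("chr1", 100L, 200L)
  ev <- detect_cryptic(junctions, introns, design, w = 50L)
  expect_equal(nrow(ev), 0L)
})
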