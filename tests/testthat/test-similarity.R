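test_that("density_mask retains ceil(density * n(n-1)/2) largest edges", {
  # 4-node toy, upper-tri (column-major): (1,2)=10 (1,3)=9 (2,3)=3 (1,4)=8
  # (2,4)=2 (3,4)=1 ; density 0.5 keeps the 3 largest: (1,2),(1,3),(1,4)
  w <- connectome(sym_from_upper(4, c(10, 9, 3, 8, 2, 1)), "s", 1, "structural")
  m <- density_mask(w, 0.5)
  expect_identical(sum(m[upper.tri(m)]), 3L)
  expect_true(m[1, 2] && m[1, 3] && m[1, 4])
  expect_identical(m, t(m))
  expect_false(any(diag(m)))

  # full density keeps every off-diagonal pair
  m1 <- density_mask(w, 1)
  expect_true(all(m1[upper.tri(m1)]))

  # 90-node matrix at 25% density keeps exactly ceil(0.25 * 4005) = 1002
  set.seed(8)
  w90 <- random_connectome(90)
  expect_identical(sum(density_mask(w90, 0.25)[upper.tri(w90)]), 1002L)

  expect_error(density_mask(w, 0), "density")
  expect_error(density_mask(w, 1.2), "density")
})

test_that("density_mask breaks ties by lexicographic node-pair order", {
  # all weights equal: the first k pairs in (i, j) order must win
  w <- connectome(sym_from_upper(4, rep(1, 6)), "s", 1, "structural")
  m <- expect_message(density_mask(w, 0.5), NA)
  expect_true(m[1, 2] && m[1, 3] && m[1, 4])
  expect_false(m[2, 3] || m[2, 4] || m[3, 4])
})

test_that("masked_spearman agrees with the rank-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  base <- function(u) connectome(sym_from_upper(4, c(u, 0)), "s", 1, "structural")
  mask <- sym_from_upper(4, c(1, 1, 1, 1, 1, 0)) > 0

  expect_equal(masked_spearman(base(x), base(x), mask), 1)
  expect_equal(masked_spearman(base(x), base(x^3), mask), 1)   # rank invariance
  expect_equal(masked_spearman(base(x), base(rev(x)), mask), -1)
  # untied ranks: 1 - 6*sum(d^2)/(n(n^2-1)) with d = (0,1,1,1,1) gives 0.8
  expect_equal(masked_spearman(base(x), base(c(1, 3, 2, 5, 4)), mask), 0.8)

  # property: matches average-rank oracle to 1e-12 on vectors of length <= 12,
  # with and without ties
  set.seed(17)
  for (len in c(4, 7, 12)) {
    for (rep in 1:20) {
      a <- sample(1:5, len, replace = TRUE) + runif(len) * (rep %% 2)
      b <- sample(1:5, len, replace = TRUE) + runif(len) * (rep %% 2)
      n <- 6  # 15 upper-tri slots >= len
      ua <- ub <- um <- numeric(15)
      ua[1:len] <- a; ub[1:len] <- b; um[1:len] <- 1
      expect_equal(
        masked_spearman(connectome(sym_from_upper(n, ua), "s", 1, "structural"),
                        connectome(sym_from_upper(n, ub), "s", 1, "structural"),
                        sym_from_upper(n, um) > 0),
        spearman_oracle(a, b), tolerance = 1e-12)
    }
  }

  expect_error(masked_spearman(base(x), base(x),
                               sym_from_upper(4, c(1, 1, 0, 0, 0, 0)) > 0),
               "fewer than 3")
})

test_that("similarity_matrix uses the row subject's timepoint-1 mask", {
  set.seed(3)
  cm <- toy_cohort_matrices(4, 12, noise = 0.05)
  s <- similarity_matrix(cm$tp1, cm$tp2, density = 0.3)
  expect_identical(dim(s$values), c(4L, 4L))
  expect_identical(rownames(s$values), cm$ids)
  # entry (i, j) recomputable with subject i's tp1 mask
  for (i in 1:4) for (j in 1:4) {
    expect_equal(s$values[i, j],
                 masked_spearman(cm$tp1[[i]], cm$tp2[[j]],
                                 density_mask(cm$tp1[[i]], 0.3)))
  }
  # union / intersection conventions differ from row but stay symmetric in mask
  su <- similarity_matrix(cm$tp1, cm$tp2, density = 0.3,
                          mask_convention = "union")
  si <- similarity_matrix(cm$tp1, cm$tp2, density = 0.6,
                          mask_convention = "intersection")
  expect_equal(su$values[cbind(1:4, 1:4)], s$values[cbind(1:4, 1:4)])
  expect_equal(su$values[1, 2],
               masked_spearman(cm$tp1[[1]], cm$tp2[[2]],
                               density_mask(cm$tp1[[1]], 0.3) |
                                 density_mask(cm$tp1[[2]], 0.3)))
  expect_equal(si$values[1, 2],
               masked_spearman(cm$tp1[[1]], cm$tp2[[2]],
                               density_mask(cm$tp1[[1]], 0.6) &
                                 density_mask(cm$tp1[[2]], 0.6)))

  # density = NULL computes the unmasked variant over all pairs
  s0 <- similarity_matrix(cm$tp1, cm$tp2, density = NULL)
  expect_equal(s0$values[2, 3],
               masked_spearman(cm$tp1[[2]], cm$tp2[[3]], NULL))

  # exchangeability: identical noise-free subjects give a constant matrix
  cm0 <- toy_cohort_matrices(1, 10, noise = 0)
  dup <- function(w, id) connectome(unclass(w), id, attr(w, "timepoint"),
                                    "structural")
  tp1 <- list(dup(cm0$tp1[[1]], "a"), dup(cm0$tp1[[1]], "b"))
  tp2 <- list(dup(cm0$tp2[[1]], "a"), dup(cm0$tp2[[1]], "b"))
  sdup <- similarity_matrix(tp1, tp2, density = 0.5)
  expect_equal(max(sdup$values) - min(sdup$values), 0)

  # subject mismatch rejected
  expect_error(similarity_matrix(cm$tp1, rev(cm$tp2), density = 0.3),
               "do not match")
})

test_that("similarity is invariant to monotone transforms of timepoint-2 weights", {
  set.seed(13)
  cm <- toy_cohort_matrices(3, 10, noise = 0.1)
  s <- similarity_matrix(cm$tp1, cm$tp2, density = 0.4)
  cube <- lapply(cm$tp2, function(w)
    connectome(unclass(w)^3, attr(w, "subject_id"), 2L, "structural"))
  s_cube <- similarity_matrix(cm$tp1, cube, density = 0.4)
  expect_equal(s$values, s_cube$values, tolerance = 1e-12)
})

test_that("identifiability applies the strict row-max criterion", {
  m <- matrix(0.5, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  diag(m) <- 1
  idf <- identifiability(m)
  expect_equal(idf$rate, 1)
  expect_equal(idf$n_matched, 3L)

  # ties are non-matches
  expect_equal(identifiability(matrix(0.7, 4, 4))$rate, 0)

  # brute-force row-scan oracle on random matrices
  set.seed(21)
  for (rep in 1:10) {
    v <- matrix(runif(36, -1, 1), 6, 6)
    expected <- sum(vapply(1:6, function(i) {
      all(v[i, i] > v[i, -i])
    }, logical(1))) / 6
    expect_equal(identifiability(v)$rate, expected)
  }
})

test_that("row-max normalization and z-scoring behave and preserve matches", {
  set.seed(9)
  cm <- toy_cohort_matrices(5, 10, noise = 0.2)
  s <- similarity_matrix(cm$tp1, cm$tp2, density = 0.5)

  nrm <- row_max_normalize(s)
  expect_equal(unname(apply(nrm$values, 1, max)), rep(1, 5))
  expect_equal(nrm$values[1, ], s$values[1, ] / max(s$values[1, ]))
  # idempotence
  expect_equal(row_max_normalize(nrm)$values, nrm$values)
  # matched subject has 1 on the diagonal
  idf <- identifiability(s)
  for (i in which(idf$matched)) expect_equal(nrm$values[i, i], 1)

  z <- zscore_rows(s)
  expect_equal(unname(rowMeans(z$values)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 5), tolerance = 1e-10)
  expect_equal(c(zscore_rows(list_to_sim(rbind(c(1, 2, 3))))$values),
               c(-1, 0, 1))

  # identifiability invariant under both transforms (and global z-scoring)
  expect_identical(identifiability(z)$matched, idf$matched)
  expect_identical(identifiability(nrm)$matched, idf$matched)
  expect_identical(identifiability(zscore_rows(s, "global"))$matched,
                   idf$matched)

  expect_error(row_max_normalize(list_to_sim(rbind(c(-1, -2, -3)))),
               "positive")
  expect_error(zscore_rows(list_to_sim(rbind(c(1, 1, 1)))), "variance")
})

test_that("threshold_sweep reports rates per density and the argmax plateau", {
  set.seed(4)
  cm <- toy_cohort_matrices(4, 12, noise = 0.02)
  sw <- threshold_sweep(cm$tp1, cm$tp2, densities = c(0.2, 0.5, 1.0))
  expect_identical(nrow(sw), 3L)
  expect_true(all(sw$rate >= 0 & sw$rate <= 1))
  expect_equal(attr(sw, "argmax"), sw$density[sw$rate == max(sw$rate)])
  # single-density sweep reduces to the plain analysis
  one <- threshold_sweep(cm$tp1, cm$tp2, densities = 1.0)
  expect_equal(one$rate,
               identifiability(similarity_matrix(cm$tp1, cm$tp2, 1.0))$rate)
  expect_error(threshold_sweep(cm$tp1, cm$tp2, densities = numeric(0)),
               "non-empty")
})
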