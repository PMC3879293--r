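# Belief-function algebra: construction, bounds, combination, pignistic.

test_that("make_bba validates and normalizes", {
  f <- ds_frame(c("a", "b"))
  certain <- make_bba(f, c("a" = 1.0))
  expect_equal(focal_sets(certain), list("a"))
  expect_equal(masses(certain), 1)

  vac <- make_bba(f, c("a,b" = 1.0))
  expect_equal(focal_sets(vac), list(c("a", "b")))
  expect_equal(vac$keys, vacuous_bba(f)$keys)

  expect_error(make_bba(f, c("a" = 0.6, "b" = 0.5)), "sum to 1")
  expect_error(make_bba(f, c("a" = -0.1, "b" = 1.1)), "negative mass")
  expect_error(make_bba(f, list(integer(0)), 1), "empty")
  expect_error(make_bba(f, c("z" = 1)), "not in frame")
  # tiny deviation is renormalized silently
  m <- make_bba(f, c("a" = 0.5 + 2e-7, "b" = 0.5))
  expect_equal(sum(masses(m)), 1, tolerance = 1e-12)
})

test_that("frame construction rejects degenerate inputs", {
  expect_error(ds_frame("a"), "at least two")
  expect_error(ds_frame(c("a", "a")), "distinct")
})

test_that("belief and plausibility match enumeration on the worked example", {
  f <- ds_frame(c("a", "b", "c"))
  m <- make_bba(f, c("a" = 0.3, "a,b" = 0.7))
  expect_equal(belief(m, c("a", "b")), 1.0)
  expect_equal(belief(m, "a"), 0.3)
  expect_equal(belief(m, c("a", "b", "c")), 1.0)
  expect_equal(belief(m, character(0)), 0.0)
  expect_equal(plausibility(m, "c"), 0.0)
  expect_equal(plausibility(m, "a"), 1.0)
  expect_equal(plausibility(m, c("a", "b", "c")), 1.0)
  expect_equal(plausibility(vacuous_bba(f), "a"), 1.0)
  expect_error(belief(m, "z"), "not in frame")
})

test_that("conflict matches pair enumeration", {
  f <- ds_frame(c("a", "b"))
  m1 <- make_bba(f, c("a" = 0.6, "a,b" = 0.4))
  m2 <- make_bba(f, c("b" = 0.5, "a,b" = 0.5))
  expect_equal(conflict(m1, m2), 0.3)
  expect_equal(conflict(m1, vacuous_bba(f)), 0)
  expect_equal(conflict(make_bba(f, c("a" = 1)), make_bba(f, c("b" = 1))), 1)
  f3 <- ds_frame(c("a", "b", "c"))
  expect_error(conflict(m1, vacuous_bba(f3)), "different frames")
})

test_that("combine reproduces the hand-enumerated orthogonal sum", {
  f <- ds_frame(c("a", "b"))
  m1 <- make_bba(f, c("a" = 0.6, "a,b" = 0.4))
  m2 <- make_bba(f, c("b" = 0.5, "a,b" = 0.5))
  m12 <- combine(m1, m2)
  expect_equal(belief(m12, "a"), 3 / 7, tolerance = 1e-12)
  expect_equal(belief(m12, "b"), 2 / 7, tolerance = 1e-12)
  expect_equal(sum(masses(m12)), 1, tolerance = 1e-12)

  # vacuous is neutral
  m2v <- combine(vacuous_bba(f), m2)
  expect_equal(m2v$keys, m2$keys)
  expect_equal(m2v$masses, m2$masses, tolerance = 1e-12)

  expect_error(combine(make_bba(f, c("a" = 1)), make_bba(f, c("b" = 1))),
               "not combinable")
})

test_that("combine agrees with the brute-force oracle on random BBAs", {
  withr::with_seed(11, {
    for (C in 2:4) for (rep in 1:40) {
      ob1 <- random_oracle_bba(C)
      ob2 <- random_oracle_bba(C)
      ref <- oracle_combine(ob1, ob2)
      if (ref$K >= 1 - 1e-12) next
      got <- as_oracle_bba(combine(as_pkg_bba(ob1, C), as_pkg_bba(ob2, C)))
      expect_equal(oracle_conflict(ob1, ob2),
                   conflict(as_pkg_bba(ob1, C), as_pkg_bba(ob2, C)),
                   tolerance = 1e-9)
      for (i in seq_along(ref$subsets))
        expect_equal(oracle_mass_of(got, ref$subsets[[i]]), ref$masses[i],
                     tolerance = 1e-9)
    }
  })
})

test_that("combine is commutative and associative", {
  withr::with_seed(12, {
    for (rep in 1:25) {
      C <- sample(2:4, 1)
      ms <- lapply(1:3, function(i) as_pkg_bba(random_oracle_bba(C), C))
      ab <- tryCatch(combine(ms[[1]], ms[[2]]), error = function(e) NULL)
      ba <- tryCatch(combine(ms[[2]], ms[[1]]), error = function(e) NULL)
      if (is.null(ab)) { expect_null(ba); next }
      expect_equal(ab$keys, ba$keys)
      expect_equal(ab$masses, ba$masses, tolerance = 1e-9)
      l <- tryCatch(combine(ab, ms[[3]]), error = function(e) NULL)
      r <- tryCatch(combine(ms[[1]], combine(ms[[2]], ms[[3]])),
                    error = function(e) NULL)
      if (!is.null(l) && !is.null(r)) {
        expect_equal(l$keys, r$keys)
        expect_equal(l$masses, r$masses, tolerance = 1e-9)
      }
    }
  })
})

test_that("combine_all folds correctly and reports the failing input", {
  f <- ds_frame(c("a", "b", "c"))
  m <- make_bba(f, c("a" = 0.3, "a,b" = 0.7))
  single <- combine_all(list(m))
  expect_equal(single$masses, m$masses)
  folded <- combine_all(list(vacuous_bba(f), vacuous_bba(f), m))
  expect_equal(folded$keys, m$keys)
  expect_equal(folded$masses, m$masses, tolerance = 1e-12)
  expect_error(
    combine_all(list(m, make_bba(f, c("c" = 1)))),
    "failed at input 2")

  # three random BBAs equal the direct triple-sum oracle
  withr::with_seed(13, {
    for (rep in 1:10) {
      obs <- lapply(1:3, function(i) random_oracle_bba(3))
      ref <- oracle_combine3(obs[[1]], obs[[2]], obs[[3]])
      if (ref$K >= 1 - 1e-12) next
      got <- tryCatch(
        as_oracle_bba(combine_all(lapply(obs, as_pkg_bba, C = 3))),
        error = function(e) NULL)
      if (is.null(got)) next  # pairwise fold hit an intermediate K = 1
      for (i in seq_along(ref$subsets))
        expect_equal(oracle_mass_of(got, ref$subsets[[i]]), ref$masses[i],
                     tolerance = 1e-9)
    }
  })
})

test_that("pignistic expands masses uniformly over members", {
  f <- ds_frame(c("a", "b", "c"))
  # Bayesian BBA: identity on probabilities
  bay <- make_bba(f, c("a" = 0.2, "b" = 0.5, "c" = 0.3))
  expect_equal(unclass(pignistic(bay)),
               c(a = 0.2, b = 0.5, c = 0.3))
  # hand expansion
  p <- pignistic(make_bba(f, c("a" = 0.4, "a,b" = 0.6)))
  expect_equal(unclass(p), c(a = 0.7, b = 0.3, c = 0.0))
  # vacuous over 4 classes -> uniform
  f4 <- ds_frame(letters[1:4])
  expect_equal(unname(unclass(pignistic(vacuous_bba(f4)))), rep(0.25, 4))
  expect_equal(pignistic_decision(p), "a")
})

test_that("belief/plausibility bounds and duality hold on random BBAs", {
  min_gap <- Inf          # min of pl - bel over everything (must be >= 0)
  max_dual <- 0           # worst |pl(A) - (1 - bel(complement))|
  max_oracle <- 0         # worst deviation from the enumeration oracle
  max_sum <- 0            # worst |sum(BetP) - 1|
  max_pig <- 0            # worst pignistic deviation from the oracle
  withr::with_seed(14, {
    for (rep in 1:1000) {
      C <- sample(2:4, 1)
      ob <- random_oracle_bba(C, max_focal = 6L)
      m <- as_pkg_bba(ob, C)
      for (A in oracle_all_subsets(C)) {
        A_chr <- as.character(A)
        bel <- belief(m, A_chr)
        pl <- plausibility(m, A_chr)
        min_gap <- min(min_gap, pl - bel)
        comp <- as.character(setdiff(seq_len(C), A))
        max_dual <- max(max_dual, abs(pl - (1 - belief(m, comp))))
        max_oracle <- max(max_oracle, abs(bel - oracle_belief(ob, A)),
                          abs(pl - oracle_plausibility(ob, A)))
      }
      p <- pignistic(m)
      max_sum <- max(max_sum, abs(sum(p) - 1))
      max_pig <- max(max_pig,
                     max(abs(unname(unclass(p)) - oracle_pignistic(ob, C))))
    }
  })
  expect_gte(min_gap, -1e-9)
  expect_lt(max_dual, 1e-9)
  expect_lt(max_oracle, 1e-9)
  expect_lt(max_sum, 1e-9)
  expect_lt(max_pig, 1e-9)
})

test_that("pignistic is equivariant under class relabeling", {
  withr::with_seed(15, {
    for (rep in 1:20) {
      C <- 4
      ob <- random_oracle_bba(C, max_focal = 6L)
      perm <- sample(C)
      # permuted BBA: subset indices mapped through perm
      obp <- list(subsets = lapply(ob$subsets, function(A) sort(perm[A])),
                  masses = ob$masses)
      p <- oracle_pignistic(ob, C)
      pp <- unname(unclass(pignistic(as_pkg_bba(obp, C))))
      expect_equal(pp[perm], p, tolerance = 1e-9)
    }
  })
})

test_that("BBA text serialization round-trips", {
  f <- ds_frame(c("left", "right", "word"))
  m <- make_bba(f, c("left" = 1 / 3, "left,word" = 0.2,
                     "left,right,word" = 1 - 1 / 3 - 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bba(m, path)
  m2 <- read_bba(path)
  expect_identical(m2$frame$classes, f$classes)
  expect_identical(m2$keys, m$keys)
  expect_equal(m2$masses, m$masses, tolerance = 1e-15)
})
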