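# Independent reference implementations used as oracles. These deliberately
# share no code with the package: belief functions are represented as plain
# lists of integer index sets, and every quantity is computed by explicit
# enumeration.

# All nonempty subsets of 1..C as a list of integer vectors.
oracle_all_subsets <- function(C) {
  out <- list()
  for (mask in 1:(2^C - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(C - 1))) > 0)
    out[[length(out) + 1L]] <- idx
  }
  out
}

# Oracle BBA: list(subsets = list of integer vectors, masses = numeric).
oracle_belief <- function(ob, A) {
  s <- 0
  for (i in seq_along(ob$subsets)) {
    B <- ob$subsets[[i]]
    if (length(B) > 0 && all(B %in% A)) s <- s + ob$masses[i]
  }
  s
}

oracle_plausibility <- function(ob, A) {
  s <- 0
  for (i in seq_along(ob$subsets))
    if (length(intersect(ob$subsets[[i]], A)) > 0) s <- s + ob$masses[i]
  s
}

oracle_conflict <- function(ob1, ob2) {
  K <- 0
  for (i in seq_along(ob1$subsets)) for (j in seq_along(ob2$subsets))
    if (length(intersect(ob1$subsets[[i]], ob2$subsets[[j]])) == 0)
      K <- K + ob1$masses[i] * ob2$masses[j]
  K
}

# Dempster combination by explicit double loop over all subset pairs.
oracle_combine <- function(ob1, ob2) {
  acc <- list()
  K <- 0
  for (i in seq_along(ob1$subsets)) for (j in seq_along(ob2$subsets)) {
    inter <- intersect(ob1$subsets[[i]], ob2$subsets[[j]])
    p <- ob1$masses[i] * ob2$masses[j]
    if (length(inter) == 0) K <- K + p
    else {
      key <- paste(sort(inter), collapse = ",")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
    }
  }
  subsets <- lapply(names(acc), function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  list(subsets = subsets, masses = unlist(acc, use.names = FALSE) / (1 - K),
       K = K)
}

# Triple combination by direct triple sum (no pairwise folding).
oracle_combine3 <- function(ob1, ob2, ob3) {
  acc <- list()
  K <- 0
  for (i in seq_along(ob1$subsets))
    for (j in seq_along(ob2$subsets))
      for (l in seq_along(ob3$subsets)) {
        inter <- intersect(intersect(ob1$subsets[[i]], ob2$subsets[[j]]),
                           ob3$subsets[[l]])
        p <- ob1$masses[i] * ob2$masses[j] * ob3$masses[l]
        if (length(inter) == 0) K <- K + p
        else {
          key <- paste(sort(inter), collapse = ",")
          acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
        }
      }
  subsets <- lapply(names(acc), function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  list(subsets = subsets, masses = unlist(acc, use.names = FALSE) / (1 - K),
       K = K)
}

oracle_pignistic <- function(ob, C) {
  p <- numeric(C)
  for (i in seq_along(ob$subsets)) {
    A <- ob$subsets[[i]]
    p[A] <- p[A] + ob$masses[i] / length(A)
  }
  p
}

# Random normal BBA on a frame of size C: a random selection of nonempty
# subsets with Dirichlet-like masses.
random_oracle_bba <- function(C, max_focal = 4L) {
  all_sub <- oracle_all_subsets(C)
  n <- sample(seq_len(min(max_focal, length(all_sub))), 1)
  pick <- sample(seq_along(all_sub), n)
  w <- stats::rexp(n)
  list(subsets = all_sub[pick], masses = w / sum(w))
}

# Convert an oracle BBA to a package bba on frame classes "1".."C".
as_pkg_bba <- function(ob, C) {
  make_bba(ds_frame(as.character(seq_len(C))), ob$subsets, ob$masses)
}

# Convert a package bba back to the oracle form (via exported accessors).
as_oracle_bba <- function(m) {
  list(subsets = lapply(focal_sets(m), as.integer), masses = masses(m))
}

# Mass of a given subset in an oracle BBA (0 if absent).
oracle_mass_of <- function(ob, A) {
  for (i in seq_along(ob$subsets))
    if (setequal(ob$subsets[[i]], A)) return(ob$masses[i])
  0
}

# Independent inter-rater agreement reference: literal per-pair averaging
# form. For L classifiers, kappa equals 1 - (average over samples of
# l_j(L-l_j)) / (N-normalizing denominator); coded here from scratch with
# explicit loops.
oracle_kappa <- function(correct) {
  L <- nrow(correct); N <- ncol(correct)
  pbar <- sum(correct) / (L * N)
  num <- 0
  for (j in seq_len(N)) {
    lj <- sum(correct[, j])
    num <- num + lj * (L - lj)
  }
  1 - num / (N * L * (L - 1) * pbar * (1 - pbar))
}

# Small helpers for data fixtures -------------------------------------------

# Deterministic linearly separable two-class toy in 2-D.
separable_toy <- function(n_per = 20, gap = 6, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
               matrix(rnorm(2 * n_per), ncol = 2) + gap)
    list(x = x, y = rep(1:2, each = n_per))
  })
}
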