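# Belief-function algebra: frames of discernment, basic belief assignments,
# belief/plausibility, Dempster's rule, and the pignistic decision layer.
# Subsets of the frame are encoded as bitmasks over the frame's fixed class
# order, so set identity is exact and intersection is a single bitwAnd.

#' Frame of discernment
#'
#' A frame of discernment is the finite ordered set of mutually exclusive and
#' exhaustive class hypotheses over which evidence is expressed. The order of
#' `classes` is fixed and defines the canonical encoding of subsets.
#'
#' @param classes vector (coerced to character) of at least two distinct class
#'   identifiers.
#' @return an object of class `ds_frame`.
#' @examples
#' ds_frame(c("left", "right", "word"))
#' @export
ds_frame <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 2L)
    stop("a frame needs at least two classes")
  if (anyDuplicated(classes))
    stop("frame classes must be distinct")
  if (length(classes) > 30L)
    stop("frames larger than 30 classes are not supported by the bitmask encoding")
  structure(list(classes = classes), class = "ds_frame")
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("<ds_frame> {", paste(x$classes, collapse = ", "), "}\n")
  invisible(x)
}

frame_size <- function(frame) length(frame$classes)

same_frame <- function(f1, f2) identical(f1$classes, f2$classes)

# -- subset encoding ---------------------------------------------------------

# Resolve a user-facing subset (class labels or 1-based indices) to a sorted
# integer index vector within the frame.
subset_indices <- function(frame, A) {
  if (is.numeric(A)) {
    idx <- as.integer(A)
    if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > frame_size(frame))))
      stop("subset indices out of frame range: ", paste(A, collapse = ","))
  } else {
    idx <- match(as.character(A), frame$classes)
    if (anyNA(idx))
      stop("subset members not in frame: ",
           paste(setdiff(as.character(A), frame$classes), collapse = ","))
  }
  if (anyDuplicated(idx)) stop("subset members must be distinct")
  sort(idx)
}

subset_mask <- function(idx) {
  if (!length(idx)) return(0L)
  sum(bitwShiftL(1L, idx - 1L))
}

mask_indices <- function(mask) which(bitwAnd(bitwShiftR(mask, 0:29), 1L) == 1L)

mask_size <- function(mask) sum(bitwAnd(bitwShiftR(mask, 0:29), 1L))

mask_labels <- function(frame, mask) frame$classes[mask_indices(mask)]

# -- construction ------------------------------------------------------------

#' Construct a basic belief assignment
#'
#' A basic belief assignment (BBA, or mass function) allocates unit belief
#' mass to nonempty subsets (focal elements) of a frame of discernment. Mass
#' on a non-singleton subset encodes belief committed to the disjunction of
#' its members without further subdivision. Only normal BBAs (no mass on the
#' empty set) are representable.
#'
#' Masses must be nonnegative and sum to 1; a deviation of at most `1e-6` is
#' silently renormalized, anything larger is rejected.
#'
#' @param frame a [ds_frame()].
#' @param assignments either a named numeric vector whose names are
#'   comma-separated class identifiers (e.g. `c("a" = 0.6, "a,b" = 0.4)`), or
#'   a list of subsets (label or index vectors) with masses given in
#'   `masses`.
#' @param masses numeric vector of masses, required iff `assignments` is a
#'   list of subsets.
#' @return an object of class `bba`.
#' @examples
#' f <- ds_frame(c("a", "b", "c"))
#' make_bba(f, c("a" = 0.3, "a,b" = 0.7))
#' @export
make_bba <- function(frame, assignments, masses = NULL) {
  stopifnot(inherits(frame, "ds_frame"))
  if (is.list(assignments)) {
    subsets <- assignments
    if (is.null(masses) || length(masses) != length(subsets))
      stop("when `assignments` is a list of subsets, `masses` must match its length")
  } else {
    if (is.null(names(assignments)))
      stop("named numeric `assignments` required (names = comma-separated class ids)")
    subsets <- strsplit(names(assignments), ",", fixed = TRUE)
    masses <- unname(assignments)
  }
  keys <- integer(length(subsets))
  for (i in seq_along(subsets)) {
    idx <- subset_indices(frame, subsets[[i]])
    if (!length(idx))
      stop("focal element ", i, " is empty: only normal BBAs (m(empty) = 0) are allowed")
    keys[i] <- subset_mask(idx)
  }
  if (anyDuplicated(keys)) {
    masses <- as.numeric(tapply(masses, keys, sum))
    keys <- sort(unique(keys))
  }
  bad <- which(masses < 0)
  if (length(bad))
    stop("negative mass on subset {",
         paste(mask_labels(frame, keys[bad[1L]]), collapse = ","), "}")
  s <- sum(masses)
  if (abs(s - 1) > 1e-6)
    stop(sprintf("masses must sum to 1 (got %.8g); largest focal {%s}",
                 s, paste(mask_labels(frame, keys[which.max(masses)]), collapse = ",")))
  new_bba(frame, keys, masses / s)
}

# Internal constructor; assumes validated, normalized input.
new_bba <- function(frame, keys, masses) {
  keep <- masses > 0
  keys <- keys[keep]; masses <- masses[keep]
  o <- order(keys)
  structure(list(frame = frame, keys = keys[o], masses = masses[o]),
            class = "bba")
}

#' @export
print.bba <- function(x, digits = 4, ...) {
  cat("<bba> on {", paste(x$frame$classes, collapse = ", "), "}\n")
  for (i in seq_along(x$keys))
    cat(sprintf("  m({%s}) = %.*g\n",
                paste(mask_labels(x$frame, x$keys[i]), collapse = ","),
                digits, x$masses[i]))
  invisible(x)
}

#' Vacuous BBA (total ignorance)
#'
#' All mass on the full frame; the neutral element of Dempster's rule.
#'
#' @param frame a [ds_frame()].
#' @export
vacuous_bba <- function(frame) {
  new_bba(frame, subset_mask(seq_len(frame_size(frame))), 1)
}

#' Focal elements of a BBA
#'
#' @param m a `bba`.
#' @return a list of character vectors of class labels, one per focal
#'   element, with the masses as an attribute-free parallel numeric vector in
#'   `masses(m)`.
#' @export
focal_sets <- function(m) {
  lapply(m$keys, mask_labels, frame = m$frame)
}

#' @rdname focal_sets
#' @export
masses <- function(m) m$masses

# -- belief / plausibility ---------------------------------------------------

#' Belief and plausibility of a subset
#'
#' Belief is the total mass committed to subsets of `A` (a lower probability
#' bound); plausibility is the total mass not contradicting `A` (an upper
#' bound). For normal BBAs `pl(A) = 1 - bel(complement of A)`.
#'
#' @param m a `bba`.
#' @param A a subset of the frame, as class labels or 1-based indices; may be
#'   empty.
#' @return a number in `[0, 1]`.
#' @export
belief <- function(m, A) {
  a <- subset_mask(subset_indices(m$frame, A))
  sum(m$masses[bitwAnd(m$keys, a) == m$keys])
}

#' @rdname belief
#' @export
plausibility <- function(m, A) {
  a <- subset_mask(subset_indices(m$frame, A))
  sum(m$masses[bitwAnd(m$keys, a) != 0L])
}

# -- combination -------------------------------------------------------------

#' Conflict mass between two BBAs
#'
#' The total product mass assigned by the pair to disjoint focal elements:
#' the `K` renormalized away by Dempster's rule. `K = 1` means total
#' conflict (the pair is not combinable).
#'
#' @param m1,m2 `bba` objects on the same frame.
#' @return a number in `[0, 1]`.
#' @export
conflict <- function(m1, m2) {
  check_same_frame(m1, m2)
  inter <- outer(m1$keys, m2$keys, bitwAnd)
  prod <- outer(m1$masses, m2$masses)
  sum(prod[inter == 0L])
}

check_same_frame <- function(m1, m2) {
  if (!same_frame(m1$frame, m2$frame))
    stop("BBAs are defined on different frames")
  invisible(TRUE)
}

#' Dempster's rule of combination (orthogonal sum)
#'
#' Conjunctive combination of two independent bodies of evidence: products of
#' masses are pooled on the intersections of their focal elements and the
#' conflicting (empty-intersection) mass `K` is renormalized away. The
#' operation is commutative and associative; the vacuous BBA is its neutral
#' element.
#'
#' Two BBAs are combinable only if some pair of focal elements intersects;
#' numerically, `K >= 1 - 1e-12` is treated as non-combinable. After
#' combination, masses below `prune` are dropped and the result renormalized
#' to bound focal-set growth.
#'
#' @param m1,m2 `bba` objects on the same frame.
#' @param prune drop threshold for negligible combined masses (default
#'   `1e-15`).
#' @return the combined `bba`.
#' @examples
#' f <- ds_frame(c("a", "b"))
#' combine(make_bba(f, c("a" = 0.6, "a,b" = 0.4)),
#'         make_bba(f, c("b" = 0.5, "a,b" = 0.5)))
#' @export
combine <- function(m1, m2, prune = 1e-15) {
  check_same_frame(m1, m2)
  inter <- outer(m1$keys, m2$keys, bitwAnd)
  prod <- outer(m1$masses, m2$masses)
  K <- sum(prod[inter == 0L])
  if (K >= 1 - 1e-12)
    stop(sprintf("BBAs are not combinable: conflict K = %.15g", K))
  keep <- inter != 0L
  agg <- tapply(prod[keep], inter[keep], sum)
  keys <- as.integer(names(agg))
  mass <- as.numeric(agg) / (1 - K)
  big <- mass >= prune
  new_bba(m1$frame, keys[big], mass[big] / sum(mass[big]))
}

#' Combine a sequence of BBAs
#'
#' Left fold of [combine()]; associativity makes the result independent of
#' the fold order (up to round-off).
#'
#' @param ms nonempty list of `bba` objects on a common frame.
#' @param prune passed to [combine()].
#' @return the combined `bba`.
#' @export
combine_all <- function(ms, prune = 1e-15) {
  if (!length(ms)) stop("need at least one BBA")
  out <- ms[[1L]]
  for (i in seq_along(ms)[-1L]) {
    out <- tryCatch(combine(out, ms[[i]], prune = prune),
                    error = function(e)
                      stop("combination failed at input ", i, ": ",
                           conditionMessage(e), call. = FALSE))
  }
  out
}

# -- pignistic layer ---------------------------------------------------------

#' Pignistic transformation
#'
#' Converts a (normal) BBA into a probability distribution for decision
#' making by splitting each focal mass uniformly among its members:
#' `BetP(w) = sum over focal A containing w of m(A) / |A|`.
#'
#' @param m a `bba`.
#' @return an object of class `pignistic`: a named probability vector over
#'   the frame classes (sums to 1).
#' @examples
#' f <- ds_frame(c("a", "b", "c"))
#' pignistic(make_bba(f, c("a" = 0.4, "a,b" = 0.6)))
#' @export
pignistic <- function(m) {
  C <- frame_size(m$frame)
  p <- numeric(C)
  for (i in seq_along(m$keys)) {
    idx <- mask_indices(m$keys[i])
    p[idx] <- p[idx] + m$masses[i] / length(idx)
  }
  structure(stats::setNames(p, m$frame$classes), class = "pignistic")
}

#' @export
print.pignistic <- function(x, digits = 4, ...) {
  cat("<pignistic>\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Decide a class from a pignistic distribution
#'
#' Argmax with deterministic tie-breaking toward the lowest class index.
#'
#' @param p a `pignistic` distribution.
#' @return the winning class label (character scalar).
#' @export
pignistic_decision <- function(p) {
  names(p)[which.max(p)]
}

# -- plain-text serialization ------------------------------------------------

#' Read and write BBAs as plain text
#'
#' One line per focal element, `class_id[,class_id...]<TAB>mass`, preceded by
#' a header line naming the frame. Masses are written with 17 significant
#' digits so the round trip is exact.
#'
#' @param m a `bba`.
#' @param path file path.
#' @return `read_bba` returns a `bba`; `write_bba` returns `path`
#'   invisibly.
#' @export
write_bba <- function(m, path) {
  lines <- c(paste0("frame\t", paste(m$frame$classes, collapse = ",")),
             vapply(seq_along(m$keys), function(i)
               sprintf("%s\t%.17g",
                       paste(mask_labels(m$frame, m$keys[i]), collapse = ","),
                       m$masses[i]), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bba
#' @export
read_bba <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 2L || hdr[1L] != "frame")
    stop("malformed BBA file: missing frame header")
  frame <- ds_frame(strsplit(hdr[2L], ",", fixed = TRUE)[[1L]])
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  subsets <- lapply(body, function(f) strsplit(f[1L], ",", fixed = TRUE)[[1L]])
  mass <- vapply(body, function(f) as.numeric(f[2L]), numeric(1))
  make_bba(frame, subsets, mass)
}
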