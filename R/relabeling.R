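# Confidence relabeling: revise crisp training labels into crisp or soft
# (set-valued) labels according to how confidently a network trained on the
# original labels classifies each training sample, plus the KNN-relabeling
# baseline that does the same from a purely local neighborhood view.

# -- soft labels -------------------------------------------------------------

# A soft label is a strictly increasing integer vector of original class
# indices; a singleton is a crisp label.

as_soft_label <- function(x, n_classes) {
  v <- sort(unique(as.integer(x)))
  if (!length(v) || any(v < 1L) || any(v > n_classes))
    stop("soft label members must be a nonempty subset of 1..", n_classes)
  v
}

soft_label_key <- function(v) paste(v, collapse = "|")

parse_soft_label <- function(s, n_classes) {
  as_soft_label(strsplit(s, "|", fixed = TRUE)[[1L]], n_classes)
}

# Canonical ordering of an expanded class list: crisp (singleton) labels
# first in class order, then soft labels ordered by their member tuples.
# Deterministic, so expert output-node semantics are reproducible.
canonical_class_list <- function(labels) {
  uniq <- unique(lapply(labels, as.integer))
  sizes <- lengths(uniq)
  key <- vapply(uniq, function(v) paste(sprintf("%04d", v), collapse = ","),
                character(1))
  uniq[order(sizes > 1L, key)]
}

labels_to_soft <- function(labels, n_classes) {
  if (is.list(labels)) lapply(labels, as_soft_label, n_classes = n_classes)
  else lapply(as.integer(labels), as_soft_label, n_classes = n_classes)
}

# -- configuration -----------------------------------------------------------

#' Relabeling configuration
#'
#' `theta` is the uncertainty threshold: classes whose closeness score
#' exceeds `theta` enter the sample's label, so smaller `theta` admits more
#' (softer) labels and `theta >= 1` forces every label crisp. `epsilon`
#' guards the score against division by zero and keeps it positive at a
#' confidence gap of zero; the reference experiments use 0.01.
#'
#' @param theta threshold in (0, Inf); values >= 1 yield only crisp labels.
#' @param epsilon small positive constant (default 0.01).
#' @return a list of class `relabel_config`.
#' @export
relabel_config <- function(theta = 0.5, epsilon = 0.01) {
  stopifnot(theta > 0, epsilon > 0)
  structure(list(theta = theta, epsilon = epsilon), class = "relabel_config")
}

# -- confidence relabeling ---------------------------------------------------

#' Per-class confidence template of a trained network
#'
#' Element `i` of the template is the mean activation of output node `i`
#' over the training samples whose original label is class `i`: the level of
#' confidence the network typically reaches on members of that class.
#'
#' @param fit a fitted network as returned by the internal MLP engine (with
#'   `C` output nodes over the original classes).
#' @param features training feature matrix.
#' @param labels integer vector of original crisp labels (1..C).
#' @return numeric vector of length `C`.
#' @export
fit_confidence_template <- function(fit, features, labels) {
  template_from_outputs(mlp_predict_out(fit, features), as.integer(labels),
                        fit$k)
}

# The template arithmetic proper: values[i] = mean of output node i over the
# samples whose original label is class i.
template_from_outputs <- function(O, labels, C) {
  counts <- tabulate(labels, nbins = C)
  if (any(counts == 0L))
    stop("class ", which(counts == 0L)[1L], " has no training samples")
  vapply(seq_len(C), function(i) mean(O[labels == i, i]), numeric(1))
}

# Closeness score of Step 4: equals 1 at the smallest confidence gap,
# stays positive at a gap of zero thanks to epsilon, and decreases strictly
# as the gap grows. Pluggable via the `score` argument of the relabeling
# functions.
default_relabel_score <- function(D, d_min, epsilon) {
  (d_min + epsilon) / (D + epsilon)
}

# Core of the relabeling rule, operating on an output matrix (rows =
# samples). Returns a list of soft labels.
confidence_relabel_outputs <- function(O, template, cfg, score = NULL) {
  if (ncol(O) != length(template))
    stop("output vector length ", ncol(O), " does not match template length ",
         length(template))
  if (is.null(score)) score <- default_relabel_score
  apply_one <- function(o) {
    D <- template - o
    D[D < 0] <- 0                       # confident class: gap clamped to zero
    d_min <- min(D)
    v <- score(D, d_min, cfg$epsilon)
    S <- which(v > cfg$theta)
    if (length(S) > 1L) S else which.min(D)
  }
  lapply(seq_len(nrow(O)), function(i) as.integer(apply_one(O[i, ])))
}

#' Relabel a single sample by network confidence
#'
#' Computes the gap `D = template - output` (negative gaps clamped to zero),
#' scores each class by `(min(D) + epsilon) / (D_i + epsilon)`, and returns
#' the set of classes scoring above `theta`; if fewer than two classes
#' qualify the sample keeps a crisp label, the class with the smallest gap
#' (ties to the lowest index).
#'
#' @param fit the relabeling network.
#' @param template its confidence template ([fit_confidence_template()]).
#' @param x a single feature vector.
#' @param cfg a [relabel_config()].
#' @param score optional replacement for the closeness score, a
#'   `function(D, d_min, epsilon)`.
#' @return an integer vector of class indices (sorted; length 1 = crisp).
#' @export
confidence_relabel <- function(fit, template, x, cfg, score = NULL) {
  O <- mlp_predict_out(fit, matrix(as.numeric(x), nrow = 1L))
  confidence_relabel_outputs(O, template, cfg, score)[[1L]]
}

#' Confidence-relabel a training set
#'
#' Trains a relabeling network on the original crisp labels, computes its
#' confidence template, and reassigns every training sample a crisp or soft
#' label. Deterministic given `mlp_cfg$seed`.
#'
#' @param features feature matrix (samples x features).
#' @param labels integer vector of original labels (1..C).
#' @param cfg a [relabel_config()].
#' @param mlp_cfg an [mlp_config()] for the relabeling network.
#' @param val_features,val_labels optional validation split used for early
#'   stopping of the relabeling network; without it the full epoch budget is
#'   used.
#' @param n_classes number of original classes (default `max(labels)`).
#' @param score optional closeness-score override (see
#'   [confidence_relabel()]).
#' @return an object of class `relabeled_dataset`: the original features,
#'   the per-sample soft labels, the expanded class list in canonical order
#'   (crisp classes first), and the fitted relabeling network and template.
#' @export
relabel_dataset <- function(features, labels, cfg, mlp_cfg,
                            val_features = NULL, val_labels = NULL,
                            n_classes = max(as.integer(labels)),
                            score = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  C <- as.integer(n_classes)
  if (C < 2L) stop("need at least two classes")
  if (any(tabulate(labels, C) == 0L)) stop("every class needs >= 1 sample")
  Y <- diag(C)[labels, , drop = FALSE]
  val_score <- NULL
  if (!is.null(val_features) && NROW(val_features) > 0L) {
    vl <- as.integer(val_labels)
    val_score <- function(Ov) mean(max.col(Ov, "first") == vl)
  }
  fit <- mlp_fit(features, Y, mlp_cfg, Xval = val_features,
                 val_score = val_score)
  template <- fit_confidence_template(fit, features, labels)
  O <- mlp_predict_out(fit, features)
  new_labels <- confidence_relabel_outputs(O, template, cfg, score)
  new_relabeled_dataset(features, new_labels, C,
                        method = "confidence",
                        network = fit, template = template, config = cfg)
}

new_relabeled_dataset <- function(features, soft_labels, n_classes, method,
                                  ...) {
  structure(list(features = features,
                 labels = soft_labels,
                 n_classes = as.integer(n_classes),
                 expanded_classes = canonical_class_list(soft_labels),
                 method = method, ...),
            class = "relabeled_dataset")
}

#' @export
print.relabeled_dataset <- function(x, ...) {
  n_soft <- sum(lengths(x$labels) > 1L)
  cat(sprintf("<relabeled_dataset> %d samples, %d original classes, %s method\n",
              length(x$labels), x$n_classes, x$method))
  cat(sprintf("  expanded classes (%d): %s\n", length(x$expanded_classes),
              paste(vapply(x$expanded_classes, soft_label_key, character(1)),
                    collapse = " ")))
  cat(sprintf("  soft-labeled samples: %d (%.1f%%)\n", n_soft,
              100 * n_soft / length(x$labels)))
  invisible(x)
}

#' Fraction of samples whose label stayed the original crisp label
#'
#' @param rd a `relabeled_dataset`.
#' @param original integer vector of original labels.
#' @return fraction in `[0, 1]`.
#' @export
crisp_retention <- function(rd, original) {
  original <- as.integer(original)
  mean(vapply(seq_along(rd$labels), function(i)
    length(rd$labels[[i]]) == 1L && rd$labels[[i]] == original[i],
    logical(1)))
}

# -- KNN relabeling baseline -------------------------------------------------

#' KNN relabeling (local-prototype baseline)
#'
#' For each training sample, its `k` nearest neighbors (Euclidean metric,
#' the sample itself excluded) are grouped by class; the mean of each class
#' group is that class's local prototype. Classes whose prototype similarity
#' to the sample exceeds `threshold` form the new soft label; if fewer than
#' two qualify the sample gets the crisp label of its most similar
#' prototype. Default similarity is `1 / (1 + distance)`.
#'
#' @param features feature matrix.
#' @param labels integer original labels.
#' @param k neighbor count (`1 <= k < n`); 5 in the reference experiments.
#' @param threshold similarity threshold for admitting a class.
#' @param similarity function mapping a Euclidean distance to a similarity.
#' @param n_classes number of original classes.
#' @return a `relabeled_dataset`.
#' @export
knn_relabel <- function(features, labels, k = 5L, threshold = 0.3,
                        similarity = function(d) 1 / (1 + d),
                        n_classes = max(as.integer(labels))) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  Dmat <- as.matrix(stats::dist(features))
  new_labels <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(Dmat[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    cls <- sort(unique(labels[nb]))
    sims <- vapply(cls, function(cc) {
      proto <- colMeans(features[nb[labels[nb] == cc], , drop = FALSE])
      similarity(sqrt(sum((features[i, ] - proto)^2)))
    }, numeric(1))
    S <- cls[sims > threshold]
    new_labels[[i]] <- if (length(S) > 1L) as.integer(S)
                       else as.integer(cls[which.max(sims)])
  }
  new_relabeled_dataset(features, new_labels, n_classes,
                        method = "knn", k = k, threshold = threshold)
}

# -- serialization -----------------------------------------------------------

#' Read and write relabeled datasets as delimited text
#'
#' Tab-separated, one row per sample: feature columns followed by a `label`
#' column holding `"i"` or `"i|j|k"` member lists.
#'
#' @param rd a `relabeled_dataset`.
#' @param path file path.
#' @param n_classes for the reader: the number of original classes used to
#'   validate member ranges (default: largest member seen).
#' @return `read_relabeled` returns a `relabeled_dataset`;
#'   `write_relabeled` returns `path` invisibly.
#' @export
write_relabeled <- function(rd, path) {
  df <- as.data.frame(rd$features)
  df$label <- vapply(rd$labels, soft_label_key, character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relabeled
#' @export
read_relabeled <- function(path, n_classes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE)
  lab_col <- as.character(df$label)
  feats <- as.matrix(df[setdiff(names(df), "label")])
  members <- lapply(strsplit(lab_col, "|", fixed = TRUE), as.integer)
  if (is.null(n_classes)) n_classes <- max(unlist(members))
  labs <- lapply(members, as_soft_label, n_classes = n_classes)
  new_relabeled_dataset(feats, labs, n_classes, method = "file")
}
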