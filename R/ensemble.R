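# The full combining classifier: per-view confidence relabeling + expert
# training, Dempster fusion of the per-view evidence, pignistic decision.
# Also the fixed-rule (average/product/maximum/minimum) and decision-template
# baseline combiners, which operate on decision profiles of plain experts
# trained on the original labels.

#' A feature-space view of a common sample set
#'
#' One representation of the same samples: a feature matrix plus the shared
#' original labels and a provenance tag (e.g. a feature index subset or
#' generator parameters).
#'
#' @param x feature matrix (samples x features).
#' @param y integer vector of original class labels (1..C).
#' @param name provenance tag.
#' @return an object of class `feature_space_view`.
#' @export
feature_space_view <- function(x, y, name = "view") {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  structure(list(x = x, y = y, name = name), class = "feature_space_view")
}

#' Ensemble configuration
#'
#' @param theta relabeling threshold (see [relabel_config()]); ignored when
#'   `theta_grid` is supplied.
#' @param epsilon relabeling guard constant (default 0.01).
#' @param relabel_mlp [mlp_config()] for the relabeling networks.
#' @param expert_mlp [mlp_config()] for the per-view experts.
#' @param theta_grid optional numeric grid; when given,
#'   [fit_evidence_ensemble()] picks the theta maximizing ensemble validation
#'   accuracy (ties to the smaller theta).
#' @param relabel_method `"confidence"` (default) or `"knn"` (the local
#'   prototype baseline).
#' @param knn_k,knn_threshold parameters of the KNN relabeler.
#' @param softmax_on passed to [train_mlp_expert()].
#' @return a list of class `ensemble_config`.
#' @export
ensemble_config <- function(theta = 0.5, epsilon = 0.01,
                            relabel_mlp = mlp_config(),
                            expert_mlp = mlp_config(),
                            theta_grid = NULL,
                            relabel_method = c("confidence", "knn"),
                            knn_k = 5L, knn_threshold = 0.3,
                            softmax_on = "raw") {
  structure(list(theta = theta, epsilon = epsilon,
                 relabel_mlp = relabel_mlp, expert_mlp = expert_mlp,
                 theta_grid = theta_grid,
                 relabel_method = match.arg(relabel_method),
                 knn_k = as.integer(knn_k), knn_threshold = knn_threshold,
                 softmax_on = softmax_on),
            class = "ensemble_config")
}

fit_ensemble_fixed_theta <- function(views, val_views, cfg, theta) {
  n_classes <- max(unlist(lapply(views, `[[`, "y")))
  rcfg <- relabel_config(theta = theta, epsilon = cfg$epsilon)
  members <- vector("list", length(views))
  for (v in seq_along(views)) {
    vw <- views[[v]]
    vv <- if (!is.null(val_views)) val_views[[v]]
    rd <- switch(cfg$relabel_method,
      confidence = relabel_dataset(vw$x, vw$y, rcfg, cfg$relabel_mlp,
                                   val_features = vv$x, val_labels = vv$y,
                                   n_classes = n_classes),
      knn = knn_relabel(vw$x, vw$y, k = cfg$knn_k,
                        threshold = cfg$knn_threshold,
                        n_classes = n_classes))
    expert <- train_mlp_expert(vw$x, rd$labels,
                               val_features = vv$x, val_labels = vv$y,
                               cfg = cfg$expert_mlp, n_classes = n_classes,
                               softmax_on = cfg$softmax_on)
    members[[v]] <- list(relabeled = rd, expert = expert, name = vw$name)
  }
  structure(list(members = members, n_classes = n_classes,
                 frame = ds_frame(as.character(seq_len(n_classes))),
                 cfg = cfg, theta = theta),
            class = "evidence_ensemble")
}

#' Fit the evidence-based combining classifier
#'
#' For each feature-space view: relabel the training samples
#' (confidence-relabeling by default), then train an expert network on the
#' relabeled data. At test time the per-view evidence is merged by
#' Dempster's rule and decided through the pignistic transformation.
#'
#' @param views list of [feature_space_view()]s indexing the same samples
#'   (shared labels).
#' @param val_views matching list of validation views (may be `NULL`).
#' @param cfg an [ensemble_config()].
#' @return an object of class `evidence_ensemble`.
#' @export
fit_evidence_ensemble <- function(views, val_views = NULL,
                                  cfg = ensemble_config()) {
  stopifnot(length(views) >= 1L)
  y0 <- views[[1L]]$y
  for (vw in views)
    if (!identical(vw$y, y0)) stop("all views must share the same labels")
  if (!is.null(val_views) && length(val_views) != length(views))
    stop("validation views must match training views")
  # theta only enters the confidence relabeler; the KNN baseline has its own
  # threshold, so the grid is skipped there
  if (is.null(cfg$theta_grid) || cfg$relabel_method == "knn")
    return(fit_ensemble_fixed_theta(views, val_views, cfg, cfg$theta))
  if (is.null(val_views))
    stop("theta_grid tuning requires validation views")
  best <- NULL; best_acc <- -Inf; best_theta <- NA_real_
  for (theta in sort(cfg$theta_grid)) {
    ens <- fit_ensemble_fixed_theta(views, val_views, cfg, theta)
    acc <- mean(predict(ens, lapply(val_views, `[[`, "x")) ==
                  val_views[[1L]]$y)
    if (acc > best_acc) {           # ties keep the smaller theta
      best <- ens; best_acc <- acc; best_theta <- theta
    }
  }
  best$val_accuracy <- best_acc
  best
}

#' @export
print.evidence_ensemble <- function(x, ...) {
  cat(sprintf("<evidence_ensemble> %d views, %d classes, theta = %g (%s relabeling)\n",
              length(x$members), x$n_classes, x$theta,
              x$cfg$relabel_method))
  for (m in x$members)
    cat(sprintf("  %s: %d output nodes\n", m$name,
                length(m$expert$class_list)))
  invisible(x)
}

#' Predict with the evidence ensemble
#'
#' Per sample: each expert emits a BBA, the BBAs are merged by Dempster's
#' rule, and the pignistic argmax over the original classes (ties to the
#' lowest index) is the decision. A BBA whose inclusion would make the
#' running conflict total (`K >= 1 - 1e-12`) is skipped with a warning
#' rather than failing the prediction.
#'
#' @param object an `evidence_ensemble`.
#' @param x_views list of feature matrices, one per view (rows = samples),
#'   or a list of single feature vectors.
#' @param type `"class"` for integer class decisions, `"pignistic"` for the
#'   full probability matrix.
#' @param ... unused.
#' @return integer vector of predicted classes, or a samples x classes
#'   matrix of pignistic probabilities.
#' @export
predict.evidence_ensemble <- function(object, x_views,
                                      type = c("class", "pignistic"), ...) {
  type <- match.arg(type)
  x_views <- lapply(x_views, function(x)
    if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x))
  n <- nrow(x_views[[1L]])
  L <- length(object$members)
  if (length(x_views) != L) stop("expected ", L, " views")
  mass <- lapply(seq_len(L), function(v)
    expert_mass_matrix(object$members[[v]]$expert, x_views[[v]]))
  C <- object$n_classes
  betp <- matrix(0, n, C, dimnames = list(NULL, object$frame$classes))
  skipped <- 0L
  for (i in seq_len(n)) {
    bbas <- lapply(seq_len(L), function(v)
      make_bba(object$frame, object$members[[v]]$expert$class_list,
               mass[[v]][i, ]))
    acc <- bbas[[1L]]
    for (v in seq_len(L)[-1L]) {
      nxt <- tryCatch(combine(acc, bbas[[v]]), error = function(e) NULL)
      if (is.null(nxt)) skipped <- skipped + 1L else acc <- nxt
    }
    betp[i, ] <- unclass(pignistic(acc))
  }
  if (skipped > 0L)
    warning(skipped, " non-combinable BBA(s) skipped at prediction time")
  if (type == "pignistic") return(betp)
  max.col(betp, "first")
}

# -- fixed-rule baselines ----------------------------------------------------

#' Combine a decision profile by a fixed rule
#'
#' The decision profile is a classifiers x classes matrix of support values
#' (rows: base classifiers; columns: the original classes). The rule
#' aggregates each class column (mean, product, max, or min) and the
#' decision is the argmax, ties to the lowest class index.
#'
#' @param profile numeric matrix (classifiers x classes).
#' @param rule one of `"average"`, `"product"`, `"maximum"`, `"minimum"`.
#' @return the winning class index (integer).
#' @export
fixed_rule_combine <- function(profile,
                               rule = c("average", "product", "maximum",
                                        "minimum")) {
  rule <- match.arg(rule)
  profile <- as.matrix(profile)
  agg <- switch(rule,
                average = colMeans(profile),
                product = apply(profile, 2L, prod),
                maximum = apply(profile, 2L, max),
                minimum = apply(profile, 2L, min))
  which.max(agg)
}

#' Decision-template combiner
#'
#' `decision_templates_fit` stores, per class, the mean decision profile of
#' its training samples; `decision_templates_predict` assigns a test profile
#' to the class whose template is nearest in squared Euclidean distance
#' (ties to the lowest class index).
#'
#' @param profiles list of decision-profile matrices, one per training
#'   sample.
#' @param labels integer class labels.
#' @return `decision_templates_fit`: an object of class
#'   `decision_templates`; `decision_templates_predict`: a class index.
#' @export
decision_templates_fit <- function(profiles, labels) {
  labels <- as.integer(labels)
  C <- max(labels)
  flat <- t(vapply(profiles, as.numeric, numeric(length(profiles[[1L]]))))
  if (any(tabulate(labels, C) == 0L))
    stop("class ", which(tabulate(labels, C) == 0L)[1L],
         " has no training samples")
  templates <- t(vapply(seq_len(C), function(cc)
    colMeans(flat[labels == cc, , drop = FALSE]),
    numeric(ncol(flat))))
  structure(list(templates = templates, dim = dim(profiles[[1L]])),
            class = "decision_templates")
}

#' @rdname decision_templates_fit
#' @param dt a fitted `decision_templates` object.
#' @param profile one decision-profile matrix.
#' @export
decision_templates_predict <- function(dt, profile) {
  v <- as.numeric(profile)
  d2 <- rowSums(sweep(dt$templates, 2L, v)^2)
  which.min(d2)
}

# -- plain (original-label) expert stack for the baselines -------------------

#' Fit per-view classifiers on original labels for the baseline combiners
#'
#' Trains one expert per view on the unmodified crisp labels (the fixed-rule
#' comparison protocol ignores relabeling) with the same architecture as the
#' evidential experts, and exposes decision profiles.
#'
#' @param views,val_views as in [fit_evidence_ensemble()].
#' @param cfg an [ensemble_config()] (only `expert_mlp` and `softmax_on` are
#'   used).
#' @return an object of class `profile_ensemble`.
#' @export
fit_profile_ensemble <- function(views, val_views = NULL,
                                 cfg = ensemble_config()) {
  n_classes <- max(unlist(lapply(views, `[[`, "y")))
  experts <- lapply(seq_along(views), function(v) {
    vv <- if (!is.null(val_views)) val_views[[v]]
    train_mlp_expert(views[[v]]$x, views[[v]]$y,
                     val_features = vv$x, val_labels = vv$y,
                     cfg = cfg$expert_mlp, n_classes = n_classes,
                     softmax_on = cfg$softmax_on)
  })
  structure(list(experts = experts, n_classes = n_classes),
            class = "profile_ensemble")
}

#' Decision profiles for a batch of samples
#'
#' @param pe a `profile_ensemble`.
#' @param x_views list of per-view feature matrices.
#' @return a list of decision-profile matrices (classifiers x classes), one
#'   per sample.
#' @export
decision_profiles <- function(pe, x_views) {
  x_views <- lapply(x_views, as.matrix)
  post <- lapply(seq_along(pe$experts), function(v)
    expert_mass_matrix(pe$experts[[v]], x_views[[v]]))
  n <- nrow(post[[1L]])
  lapply(seq_len(n), function(i)
    do.call(rbind, lapply(post, function(p) p[i, ])))
}

#' Predict with a fixed rule over a profile ensemble
#'
#' @param pe a `profile_ensemble`.
#' @param x_views list of per-view feature matrices.
#' @param rule passed to [fixed_rule_combine()].
#' @return integer vector of class decisions.
#' @export
predict_fixed_rule <- function(pe, x_views, rule = "average") {
  vapply(decision_profiles(pe, x_views), fixed_rule_combine, integer(1),
         rule = rule)
}
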