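# Per-view experts: one-hidden-layer networks trained on relabeled (crisp +
# soft) class lists, whose outputs are read as basic belief assignments over
# the original frame. Each output node of an expert corresponds to one crisp
# or soft class, i.e. to one focal subset of the frame.

#' Train an expert network over (possibly soft) labels
#'
#' Targets are one-hot over the expanded class list (zeros except for the
#' sample's crisp/soft class, which is one), output units are logistic, and
#' training stops early when validation accuracy stops improving. Validation
#' labels are original crisp labels: validation predictions are obtained by
#' converting the expert output to a BBA, applying the pignistic
#' transformation, and taking the argmax over original classes, so experts
#' with soft output nodes are scored on the original problem.
#'
#' @param features training feature matrix.
#' @param labels per-sample labels: a list of integer soft labels, or an
#'   integer vector of crisp labels.
#' @param val_features,val_labels validation split (crisp integer labels);
#'   `NULL` disables early stopping with a warning.
#' @param cfg an [mlp_config()].
#' @param n_classes number of original classes.
#' @param class_list optional expanded class list (list of soft labels) fixing
#'   output-node semantics; defaults to the canonical list of labels seen.
#' @param softmax_on where the BBA softmax is applied: `"raw"` (default, the
#'   pre-logistic output activations) or `"logistic"` (the squashed outputs).
#' @return an object of class `expert_model`.
#' @export
train_mlp_expert <- function(features, labels, val_features = NULL,
                             val_labels = NULL, cfg = mlp_config(),
                             n_classes = NULL,
                             class_list = NULL,
                             softmax_on = c("raw", "logistic")) {
  softmax_on <- match.arg(softmax_on)
  features <- as.matrix(features)
  if (is.null(n_classes))
    n_classes <- max(unlist(labels))
  soft <- labels_to_soft(labels, n_classes)
  if (is.null(class_list)) class_list <- canonical_class_list(soft)
  keys <- vapply(class_list, soft_label_key, character(1))
  node <- match(vapply(soft, soft_label_key, character(1)), keys)
  if (anyNA(node)) stop("some labels are missing from the class list")
  K <- length(class_list)
  Y <- diag(K)[node, , drop = FALSE]
  # Pignistic map: row k spreads the mass of class-list entry k uniformly
  # over its members in the original frame.
  M <- matrix(0, K, n_classes)
  for (j in seq_len(K)) M[j, class_list[[j]]] <- 1 / length(class_list[[j]])
  val_score <- NULL
  if (!is.null(val_features) && NROW(val_features) > 0L) {
    vl <- as.integer(val_labels)
    val_score <- function(Ov) mean(max.col(Ov %*% M, "first") == vl)
  }
  fit <- mlp_fit(features, Y, cfg, Xval = val_features, val_score = val_score)
  structure(list(fit = fit, class_list = class_list,
                 n_classes = as.integer(n_classes),
                 frame = ds_frame(as.character(seq_len(n_classes))),
                 pignistic_map = M, softmax_on = softmax_on,
                 epochs = fit$epochs, val_accuracy = fit$val_accuracy),
            class = "expert_model")
}

#' @export
print.expert_model <- function(x, ...) {
  cat(sprintf("<expert_model> %d inputs, %d hidden, %d output nodes over %d classes\n",
              x$fit$d, x$fit$cfg$hidden_units, length(x$class_list),
              x$n_classes))
  cat("  nodes:", paste(vapply(x$class_list, soft_label_key, character(1)),
                        collapse = " "), "\n")
  cat(sprintf("  trained %d epochs, val accuracy %.4f\n", x$epochs,
              x$val_accuracy))
  invisible(x)
}

# Row-wise mass matrix for a batch of samples (n x K), used by the ensemble.
expert_mass_matrix <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$fit$d)
    stop("feature dimension ", ncol(X), " does not match expert input ",
         model$fit$d)
  fwd <- mlp_forward(model$fit$net, X)
  softmax(if (model$softmax_on == "raw") fwd$raw else fwd$out)
}

#' Expert output as a basic belief assignment
#'
#' Applies the softmax operator to the expert's output activations for a
#' single sample; the resulting masses sit on the expert's crisp and soft
#' classes, each a focal subset of the original frame.
#'
#' @param model an `expert_model`.
#' @param x one feature vector.
#' @return a [make_bba()] object on the original frame.
#' @export
expert_bba <- function(model, x) {
  p <- expert_mass_matrix(model, matrix(as.numeric(x), nrow = 1L))[1L, ]
  make_bba(model$frame, model$class_list, p)
}

# -- serialization -----------------------------------------------------------

#' Read and write expert models as structured text
#'
#' Weights are written with 17 significant digits, so the round trip
#' restores them bit-exactly.
#'
#' @param model an `expert_model`.
#' @param path file path.
#' @return `read_expert` returns an `expert_model`; `write_expert` returns
#'   `path` invisibly.
#' @export
write_expert <- function(model, path) {
  cfg <- model$fit$cfg
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "evicomb_expert\t1",
    paste0("n_classes\t", model$n_classes),
    paste0("softmax_on\t", model$softmax_on),
    paste0("class_list\t", paste(vapply(model$class_list, soft_label_key,
                                        character(1)), collapse = " ")),
    paste0("config\t", paste(cfg$hidden_units, num(cfg$learning_rate),
                             cfg$max_epochs, cfg$patience, num(cfg$tol),
                             cfg$seed, sep = " ")),
    paste0("epochs\t", model$epochs),
    paste0("val_accuracy\t", num(model$val_accuracy)),
    paste0("dims\t", model$fit$d, " ", cfg$hidden_units, " ", model$fit$k),
    paste0("W1\t", paste(num(model$fit$net$W1), collapse = " ")),
    paste0("W2\t", paste(num(model$fit$net$W2), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_expert
#' @export
read_expert <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1L)
  get <- function(name) fields[[match(name, tag)]][2L]
  if (tag[1L] != "evicomb_expert") stop("not an expert model file")
  num_in <- function(s) if (identical(s, "NA")) NA_real_ else as.numeric(s)
  n_classes <- as.integer(get("n_classes"))
  class_list <- lapply(strsplit(get("class_list"), " ", fixed = TRUE)[[1L]],
                       parse_soft_label, n_classes = n_classes)
  cv <- strsplit(get("config"), " ", fixed = TRUE)[[1L]]
  cfg <- mlp_config(hidden_units = as.integer(cv[1L]),
                    learning_rate = as.numeric(cv[2L]),
                    max_epochs = as.integer(cv[3L]),
                    patience = as.integer(cv[4L]),
                    tol = as.numeric(cv[5L]), seed = as.integer(cv[6L]))
  dims <- as.integer(strsplit(get("dims"), " ", fixed = TRUE)[[1L]])
  W1 <- matrix(as.numeric(strsplit(get("W1"), " ", fixed = TRUE)[[1L]]),
               dims[1L] + 1L, dims[2L])
  W2 <- matrix(as.numeric(strsplit(get("W2"), " ", fixed = TRUE)[[1L]]),
               dims[2L] + 1L, dims[3L])
  K <- length(class_list)
  M <- matrix(0, K, n_classes)
  for (j in seq_len(K)) M[j, class_list[[j]]] <- 1 / length(class_list[[j]])
  structure(list(fit = list(net = list(W1 = W1, W2 = W2),
                            epochs = as.integer(get("epochs")),
                            val_accuracy = num_in(get("val_accuracy")),
                            cfg = cfg, d = dims[1L], k = dims[3L]),
                 class_list = class_list, n_classes = n_classes,
                 frame = ds_frame(as.character(seq_len(n_classes))),
                 pignistic_map = M,
                 softmax_on = get("softmax_on"),
                 epochs = as.integer(get("epochs")),
                 val_accuracy = num_in(get("val_accuracy"))),
            class = "expert_model")
}
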