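.feat_multi <- c("junction_log_ratio", "exon_intron_log_ratio",
                 "neighbor_expression", "overlap_fraction")
.feat_mono <- c("neighbor_expression", "overlap_fraction")

#' Assemble a pooled training set from stranded samples
#'
#' Joins per-sample feature tables (computed strand-blind) with the same
#' samples' strandedness labels, keeping detectable genes only, and pools
#' the (gene x sample) instances across samples.
#'
#' @param features list of [extract_features()] data.frames (or one).
#' @param labels list of matching [label_genes()] data.frames (or one).
#' @return data.frame of training instances with a `sample` index, the four
#'   metrics, `monoexonic` and the logical `affected` label.
#' @export
sb_training_set <- function(features, labels) {
  if (is.data.frame(features)) features <- list(features)
  if (is.data.frame(labels)) labels <- list(labels)
  stopifnot(length(features) == length(labels))
  out <- lapply(seq_along(features), function(i) {
    f <- features[[i]]; l <- labels[[i]]
    m <- match(f$gene_id, l$gene_id)
    if (anyNA(m)) stop("sample ", i, ": features and labels disagree on genes")
    keep <- l$detectable[m]
    cbind(sample = i, f[keep, , drop = FALSE],
          affected = l$affected[m][keep])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Train the strand-bias decision trees
#'
#' Fits two depth-limited classification trees predicting whether a gene's
#' unstranded count is inflated by opposite-strand transcription: one for
#' multiexonic genes on all four metrics (depth at most 5) and one for
#' monoexonic genes on neighbor expression and overlap fraction only (depth
#' at most 3) — one more than the number of features in each case. Because
#' affected genes are a small minority (roughly 10% of detectable genes),
#' instances are class-balance weighted by default, which stabilizes the
#' leaf class fractions used as scores. Training is deterministic given the
#' seed and instance order.
#'
#' @param training a [sb_training_set()] data.frame (gene x sample
#'   instances with an `affected` label).
#' @param seed integer seed recorded in the model and set before fitting.
#' @param max_depth named depths for the two trees.
#' @param balance class-balance the instance weights (default `TRUE`); with
#'   `FALSE` leaf probabilities are raw training-instance fractions.
#' @param min_split minimum instances in a node for a split (default 20).
#' @return object of class `strand_bias_model` with components
#'   `tree_multiexonic`, `tree_monoexonic` (rpart fits) and training
#'   metadata; use [predict.strand_bias_model()] to score genes and
#'   [save_model()] to persist it.
#' @seealso [default_model()] for a ready-made model trained on the
#'   synthetic corpus.
#' @export
sb_train <- function(training, seed = 1L,
                     max_depth = c(multiexonic = 5L, monoexonic = 3L),
                     balance = TRUE, min_split = 20L) {
  stopifnot(is.data.frame(training),
            all(c(.feat_multi, "monoexonic", "affected") %in% names(training)))
  fit_one <- function(dat, feats, depth) {
    if (nrow(dat) == 0L) return(NULL)
    y <- factor(ifelse(dat$affected, "affected", "unaffected"),
                levels = c("unaffected", "affected"))
    if (nlevels(droplevels(y)) < 2L)
      stop("training data contain a single class (",
           as.character(unique(y)), ") for this gene stratum")
    w <- if (balance) {
      tab <- table(y)
      as.numeric(length(y) / (2 * tab[y]))
    } else rep(1, length(y))
    df <- dat[, feats, drop = FALSE]
    df$.y <- y
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = depth, cp = 0, xval = 0,
                          minsplit = min_split))
    ## strip session-dependent bits so serialization is reproducible
    attr(fit$terms, ".Environment") <- baseenv()
    fit$call <- quote(rpart::rpart(.y ~ .))
    fit
  }
  set.seed(seed)
  multi <- fit_one(training[!training$monoexonic, , drop = FALSE],
                   .feat_multi, max_depth[["multiexonic"]])
  mono <- fit_one(training[training$monoexonic, , drop = FALSE],
                  .feat_mono, max_depth[["monoexonic"]])
  if (is.null(multi) && is.null(mono)) stop("empty training set")
  structure(list(tree_multiexonic = multi, tree_monoexonic = mono,
                 features = list(multiexonic = .feat_multi,
                                 monoexonic = .feat_mono),
                 max_depth = max_depth, balance = balance, seed = seed,
                 n_instances = c(multiexonic = sum(!training$monoexonic),
                                 monoexonic = sum(training$monoexonic)),
                 version = 1L),
            class = "strand_bias_model")
}

#' @export
print.strand_bias_model <- function(x, ...) {
  cat("strand_bias_model (decision trees over alignment metrics)\n")
  cat(sprintf("  multiexonic tree: depth <= %d, %d training instances\n",
              x$max_depth[["multiexonic"]], x$n_instances[["multiexonic"]]))
  cat(sprintf("  monoexonic tree:  depth <= %d, %d training instances\n",
              x$max_depth[["monoexonic"]], x$n_instances[["monoexonic"]]))
  cat("  class weighting:", if (x$balance) "balanced" else "none",
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.strand_bias_model <- function(object, ...) {
  print(object)
  for (nm in c("tree_multiexonic", "tree_monoexonic")) {
    tr <- object[[nm]]
    if (is.null(tr)) next
    cat("\n--", nm, "--\n")
    print(tr)
  }
  invisible(object)
}

#' Score genes with a trained strand-bias model
#'
#' Routes multiexonic genes to the four-feature tree and monoexonic genes
#' to the two-feature tree. For each gene `p_affected` is the (weighted)
#' fraction of affected training instances in the leaf the gene lands in,
#' and `confidence = 1 - p_affected`: 1 means the unstranded count is
#' trusted, 0 means it is very likely inflated by the opposite strand.
#'
#' @param object a [sb_train()] model.
#' @param features an [extract_features()] data.frame.
#' @param ... unused.
#' @return data.frame `gene_id`, `model_used`, `p_affected`, `confidence`.
#' @export
predict.strand_bias_model <- function(object, features, ...) {
  stopifnot(is.data.frame(features),
            all(c(.feat_multi, "monoexonic") %in% names(features)))
  n <- nrow(features)
  p <- rep(NA_real_, n)
  used <- ifelse(features$monoexonic, "monoexonic", "multiexonic")
  score <- function(tree, rows, feats, what) {
    if (!length(rows)) return()
    if (is.null(tree)) stop("model has no ", what, " tree")
    nd <- features[rows, feats, drop = FALSE]
    if (anyNA(nd))
      stop("undefined required feature(s) for ", what, " gene(s): ",
           paste(features$gene_id[rows][!stats::complete.cases(nd)][1:3],
                 collapse = ", "))
    pr <- predict(tree, newdata = nd, type = "prob")
    p[rows] <<- pr[, "affected"]
  }
  score(object$tree_multiexonic, which(!features$monoexonic), .feat_multi,
        "multiexonic")
  score(object$tree_monoexonic, which(features$monoexonic), .feat_mono,
        "monoexonic")
  data.frame(gene_id = features$gene_id, model_used = used,
             p_affected = p, confidence = 1 - p,
             row.names = features$gene_id, stringsAsFactors = FALSE)
}

#' Persist / reload a strand-bias model
#'
#' Serialization is reproducible: retraining with identical inputs and seed
#' yields a byte-identical model file.
#'
#' @param model a `strand_bias_model`.
#' @param path file path (`.rds`).
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "strand_bias_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "strand_bias_model"))
    stop(path, " does not contain a strand_bias_model")
  m
}
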