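# Evaluation: Dice similarity coefficient, the volumetric chunk-pairing
# protocol (query volumes segmented slice by slice against the centre slice
# of the corresponding support chunk), and NIfTI volume I/O.

#' Dice similarity coefficient (percentage)
#'
#' `DSC = 2 |X intersect Y| / (|X| + |Y|) * 100`. When both masks are empty
#' the score is 100 by convention (perfect agreement on absence).
#'
#' @param pred,truth binary arrays or matrices of equal shape.
#' @return value in \[0, 100\].
#' @export
#' @examples
#' dsc(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))  # 50
dsc <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("dsc: shapes disagree")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("dsc: inputs must be binary")
  }
  s <- sum(pred) + sum(truth)
  if (s == 0) return(100)
  200 * sum(pred * truth) / s
}

#' Pair query slices with support chunk centres
#'
#' Both eligible-slice index lists are divided into `n_chunks` contiguous
#' chunks of near-equal size; every query slice in chunk j is paired with the
#' centre slice (middle index, lower on ties) of support chunk j. When either
#' list has fewer slices than requested chunks, the chunk count is reduced to
#' that length with a warning.
#'
#' @param support_slices,query_slices integer vectors of eligible slice
#'   indices (slices containing the target class), in volume order.
#' @param n_chunks number of chunks; default 9.
#' @return data.frame with columns `query` and `support`.
#' @export
chunk_pairs <- function(support_slices, query_slices, n_chunks = 9L) {
  stopifnot(length(support_slices) >= 1L, length(query_slices) >= 1L)
  nc <- min(n_chunks, length(support_slices), length(query_slices))
  if (nc < n_chunks) {
    warning("chunk_pairs: fewer eligible slices than chunks; using ",
            nc, " chunks")
  }
  chunk_of <- function(x) ceiling(seq_along(x) * nc / length(x))
  qc <- chunk_of(query_slices)
  sc <- chunk_of(support_slices)
  centres <- vapply(seq_len(nc), function(j) {
    s <- support_slices[sc == j]
    s[(length(s) + 1L) %/% 2L]
  }, numeric(1))
  data.frame(query = query_slices, support = centres[qc])
}

#' Evaluate a model on held-out classes over phantom volumes
#'
#' For every test class, every volume serves once as query with the next
#' volume (cyclically) as support. Eligible slices are those whose ground
#' truth contains the class; they are paired by [chunk_pairs()], each query
#' slice is segmented in a 1-way 1-shot episode using the paired support
#' slice with its true class mask, and the predictions are restacked so the
#' Dice coefficient is computed volumetrically over the eligible stack.
#'
#' @param model a trained `protoseg_model`, or a predictor function
#'   `(support_image, support_mask, query_image) -> binary mask` (e.g. a
#'   ground-truth oracle in tests).
#' @param volumes list of `phantom_volume` objects (or lists with `image` and
#'   `labels` arrays).
#' @param test_classes integer class ids to evaluate.
#' @param n_chunks chunks for the pairing protocol; default 9.
#' @param fold optional fold id recorded in the report.
#' @return object of class `protoseg_eval`: list with `per_class_dsc`
#'   (named mean DSC per class, %), `mean_dsc` (unweighted class mean),
#'   `n_volumes`, `fold`, `config`.
#' @export
evaluate_model <- function(model, volumes, test_classes, n_chunks = 9L,
                           fold = NA_integer_) {
  predictor <- if (is.function(model)) model else {
    stopifnot(inherits(model, "protoseg_model"))
    if (!is.null(model$train_classes) &&
        any(test_classes %in% model$train_classes)) {
      stop("evaluate_model: protocol violation - model was trained on class(es) ",
           paste(intersect(test_classes, model$train_classes), collapse = ", "))
    }
    function(si, sm, qi) predict(model, si, sm, qi)
  }
  nv <- length(volumes)
  stopifnot(nv >= 2L)
  per_class <- stats::setNames(numeric(0), character(0))
  for (cl in test_classes) {
    scores <- numeric(0)
    for (q in seq_len(nv)) {
      s <- (q %% nv) + 1L
      qv <- volumes[[q]]; sv <- volumes[[s]]
      q_sl <- which(apply(qv$labels == cl, 3, any))
      s_sl <- which(apply(sv$labels == cl, 3, any))
      if (length(q_sl) == 0L || length(s_sl) == 0L) next
      pairs <- chunk_pairs(s_sl, q_sl, n_chunks)
      d <- dim(qv$labels)
      pred_stack <- array(0L, c(d[1], d[2], nrow(pairs)))
      truth_stack <- array(0L, c(d[1], d[2], nrow(pairs)))
      for (r in seq_len(nrow(pairs))) {
        zq <- pairs$query[r]; zs <- pairs$support[r]
        sm <- (sv$labels[, , zs] == cl) * 1
        pred_stack[, , r] <- predictor(sv$image[, , zs], sm, qv$image[, , zq])
        truth_stack[, , r] <- (qv$labels[, , zq] == cl) * 1L
      }
      scores <- c(scores, dsc(pred_stack, truth_stack))
    }
    per_class[as.character(cl)] <- mean(scores)
  }
  out <- list(per_class_dsc = per_class,
              mean_dsc = mean(per_class),
              n_volumes = nv, fold = fold,
              config = list(n_chunks = n_chunks, classes = test_classes))
  class(out) <- "protoseg_eval"
  out
}

#' @export
print.protoseg_eval <- function(x, ...) {
  cat("<protoseg_eval> fold", x$fold, "-", x$n_volumes, "volumes\n")
  for (nm in names(x$per_class_dsc)) {
    cat(sprintf("  class %s: %.2f%%\n", nm, x$per_class_dsc[[nm]]))
  }
  cat(sprintf("  mean DSC: %.2f%%\n", x$mean_dsc))
  invisible(x)
}

#' Read a NIfTI volume (optionally with labels) for evaluation
#'
#' Intensities are min-max normalised to \[0, 1\] per volume; when `size` is
#' given each slice is centre-cropped to `size x size`. Label volumes are
#' never normalised and are cropped identically.
#'
#' @param path NIfTI image file (.nii or .nii.gz).
#' @param label_path optional NIfTI label file.
#' @param size optional in-plane crop size.
#' @return list with `image` (H x W x D array in \[0,1\]), `labels` (integer
#'   array or NULL) and `header` (the source NIfTI header for write-back).
#' @export
read_volume <- function(path, label_path = NULL, size = NULL) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  nii <- RNifti::readNifti(path)
  img <- as.array(nii)
  attributes(img) <- list(dim = dim(img))   # plain array, no NIfTI baggage
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  crop <- function(a, size) {
    d <- dim(a)
    if (d[1] < size || d[2] < size) {
      stop("read_volume: volume smaller than crop size ", size)
    }
    y0 <- (d[1] - size) %/% 2L
    x0 <- (d[2] - size) %/% 2L
    a[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE]
  }
  if (!is.null(size)) img <- crop(img, size)
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) {
      stop("read_volume: missing label file: ", label_path)
    }
    labels <- as.array(RNifti::readNifti(label_path))
    attributes(labels) <- list(dim = dim(labels))
    storage.mode(labels) <- "integer"
    if (!is.null(size)) labels <- crop(labels, size)
  }
  list(image = img, labels = labels, header = RNifti::niftiHeader(nii))
}

#' Write a predicted label volume as NIfTI
#'
#' @param labels integer array.
#' @param path output path (.nii or .nii.gz).
#' @param reference optional NIfTI header or image supplying geometry.
#' @return invisibly, `path`.
#' @export
write_volume <- function(labels, path, reference = NULL) {
  if (!is.null(reference)) {
    RNifti::writeNifti(RNifti::asNifti(labels, reference = reference), path)
  } else {
    RNifti::writeNifti(labels, path)
  }
  invisible(path)
}
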