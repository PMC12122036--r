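# Segmentation evaluation: overlap/ratio metrics from per-image confusion
# counts, and the symmetric average Hausdorff distance between foreground
# point sets.

as_mask_list <- function(x, what = "mask") {
  if (is.list(x)) {
    masks <- lapply(x, function(m) {
      dm <- dim(m)
      if (is.null(dm)) stop("invalid input: ", what, " must be a matrix")
      if (length(dm) > 2) m <- array(m, dm[1:2])
      m
    })
  } else {
    d <- dim(x)
    if (is.null(d)) stop("invalid input: ", what, " must have dimensions")
    if (length(d) == 2) masks <- list(x)
    else if (length(d) == 4) {
      if (d[3] != 1) stop("invalid input: expected single-channel masks")
      masks <- lapply(seq_len(d[4]), function(b) array(x[, , 1, b], d[1:2]))
    } else if (length(d) == 3) {
      masks <- lapply(seq_len(d[3]), function(b) array(x[, , b], d[1:2]))
    } else stop("invalid input: unsupported ", what, " dimensions")
  }
  for (m in masks)
    if (!all(m %in% c(0, 1)))
      stop("invalid input: ", what, " is not strictly binary")
  masks
}

#' Symmetric average Hausdorff distance between two binary masks
#'
#' Half the sum of (i) the mean over predicted foreground pixels of the
#' Euclidean distance to the nearest ground-truth foreground pixel and (ii)
#' the reverse-direction mean.  Distances are in pixels.
#'
#' @param pred_mask,g binary matrices of equal size
#' @return non-negative scalar; `NA` with a warning when either mask has no
#'   foreground (the distance is undefined then)
#' @export
average_hausdorff <- function(pred_mask, g) {
  pm <- as_mask_list(pred_mask, "prediction")[[1]]
  gm <- as_mask_list(g, "ground truth")[[1]]
  if (!identical(dim(pm), dim(gm)))
    stop("invalid input: mask shapes differ")
  a <- which(pm == 1, arr.ind = TRUE)
  b <- which(gm == 1, arr.ind = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("average_hausdorff: empty foreground; distance undefined")
    return(NA_real_)
  }
  avg_hausdorff_cpp(a * 1.0, b * 1.0)
}

confusion_counts <- function(pm, gm) {
  tp <- sum(pm == 1 & gm == 1)
  fp <- sum(pm == 1 & gm == 0)
  fn <- sum(pm == 0 & gm == 1)
  tn <- sum(pm == 0 & gm == 0)
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

ratio_or_1 <- function(num, den) if (den == 0) 1 else num / den

#' Per-image and aggregate segmentation metrics
#'
#' Computes IoU, DSC, accuracy and recall from per-image confusion counts,
#' optionally with the average Hausdorff distance, and aggregates across
#' images as unweighted mean and standard deviation.  When a metric's
#' denominator is empty on both sides (e.g. both masks empty) the metric is
#' defined as 1 (perfect agreement).
#'
#' @param pred_mask binary prediction: matrix, `(H, W, 1, B)` array, or list
#'   of matrices
#' @param g binary ground truth of matching shape
#' @param ids optional per-image identifiers
#' @param hausdorff include the average Hausdorff distance column
#' @return a `metric_report`: list with `per_image` data frame and `summary`
#'   data frame (mean, sd per metric)
#' @export
segmentation_metrics <- function(pred_mask, g, ids = NULL, hausdorff = TRUE) {
  pms <- as_mask_list(pred_mask, "prediction")
  gms <- as_mask_list(g, "ground truth")
  if (length(pms) != length(gms))
    stop("invalid input: differing image counts")
  n <- length(pms)
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    pm <- pms[[i]]; gm <- gms[[i]]
    if (!identical(dim(pm), dim(gm)))
      stop("invalid input: mask shapes differ for image ", ids[i])
    cc <- confusion_counts(pm, gm)
    r <- data.frame(
      id = ids[i],
      iou = ratio_or_1(cc["tp"], cc["tp"] + cc["fp"] + cc["fn"]),
      dsc = ratio_or_1(2 * cc["tp"], 2 * cc["tp"] + cc["fp"] + cc["fn"]),
      acc = (cc["tp"] + cc["tn"]) / sum(cc),
      rec = ratio_or_1(cc["tp"], cc["tp"] + cc["fn"]))
    if (hausdorff) {
      r$avg_hausdorff <- if (sum(pm) == 0 && sum(gm) == 0) 0
      else if (sum(pm) == 0 || sum(gm) == 0) {
        warning("empty foreground for image ", ids[i],
                "; Hausdorff undefined")
        NA_real_
      } else avg_hausdorff_cpp(which(pm == 1, arr.ind = TRUE) * 1.0,
                               which(gm == 1, arr.ind = TRUE) * 1.0)
    }
    r
  })
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  cols <- setdiff(names(per_image), "id")
  summary <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cn) mean(per_image[[cn]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(cols, function(cn) stats::sd(per_image[[cn]], na.rm = TRUE),
                numeric(1)))
  rownames(summary) <- NULL
  structure(list(per_image = per_image, summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_image), "image(s):\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-14s %.4f ± %.4f\n", s$metric, s$mean,
                ifelse(is.na(s$sd), 0, s$sd)))
  }
  invisible(x)
}

#' Write a metric report as a delimited file
#'
#' One row per image plus a trailing summary row (`mean +/- sd`).
#'
#' @param report a `metric_report`
#' @param path output file (tab-separated)
#' @export
write_metric_report <- function(report, path) {
  pi <- report$per_image
  s <- report$summary
  summary_row <- pi[1, , drop = FALSE]
  summary_row$id <- "mean+/-sd"
  for (cn in s$metric)
    summary_row[[cn]] <- sprintf("%.4f+/-%.4f", s$mean[s$metric == cn],
                                 ifelse(is.na(s$sd[s$metric == cn]), 0,
                                        s$sd[s$metric == cn]))
  out <- rbind(data.frame(lapply(pi, as.character),
                          stringsAsFactors = FALSE),
               data.frame(lapply(summary_row, as.character),
                          stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
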