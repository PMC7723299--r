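# Cell Tracking Challenge file conventions: label masks as one 16-bit
# TIFF per frame (`mask{T}.tif`, zero-padded frame index), lineages as
# plain-text `res_track.txt` / `man_track.txt` with one `L B E P` line
# per track, and the Jaccard-based SEG evaluation measure.

pad_width <- function(n_frames) max(3L, nchar(as.character(n_frames - 1L)))

#' Write a lineage text file
#'
#' One line `L B E P` per track (label, first frame, last frame, parent
#' label with 0 = none), space separated.
#'
#' @param records data.frame with columns `L`, `B`, `E`, `P`, or a
#'   `cell_lineage` object.
#' @param path output file (conventionally `res_track.txt`).
#' @export
write_lineage <- function(records, path) {
  if (inherits(records, "cell_lineage")) records <- lineage_records(records)
  check_lineage_records(records)
  lines <- sprintf("%d %d %d %d", records$L, records$B, records$E,
                   records$P)
  writeLines(lines, path)
  invisible(path)
}

#' Read a lineage text file
#'
#' @param path file with `L B E P` lines.
#' @return data.frame with columns `L`, `B`, `E`, `P`.
#' @export
read_lineage <- function(path) {
  m <- utils::read.table(path, col.names = c("L", "B", "E", "P"))
  check_lineage_records(m)
  m
}

check_lineage_records <- function(r) {
  stopifnot(all(c("L", "B", "E", "P") %in% names(r)))
  if (any(r$B > r$E)) stop("lineage record with begin > end")
  if (any(r$P == r$L)) stop("track cannot be its own parent")
  withp <- r[r$P > 0, , drop = FALSE]
  if (nrow(withp)) {
    pe <- r$E[match(withp$P, r$L)]
    if (any(is.na(pe))) stop("parent id not present in lineage")
    if (any(pe >= withp$B)) stop("parent must end before child begins")
  }
  invisible(r)
}

#' Write a mask sequence as 16-bit TIFFs
#'
#' Files are named `<prefix><T>.tif` with zero-padded 0-based frame index
#' (pad width at least 3). Integer labels survive a read/write round trip
#' losslessly, including labels above 255.
#'
#' @param frames list of integer label images.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix, default `"mask"`.
#' @export
write_mask_sequence <- function(frames, dir, prefix = "mask") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- pad_width(length(frames))
  for (t in seq_along(frames)) {
    f <- file.path(dir, sprintf("%s%0*d.tif", prefix, w, t - 1L))
    m <- frames[[t]]
    if (max(m) > 65535) stop("labels exceed 16-bit range")
    tiff::writeTIFF(m / 65535, f, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(dir)
}

#' Read a mask sequence
#'
#' @param dir directory with `<prefix><T>.tif` files.
#' @param prefix filename prefix, default `"mask"`.
#' @return list of integer label images ordered by frame index.
#' @export
read_mask_sequence <- function(dir, prefix = "mask") {
  files <- list.files(dir, pattern = paste0("^", prefix, "[0-9]+\\.tiff?$"),
                      full.names = TRUE)
  if (!length(files)) stop("no ", prefix, "*.tif files in ", dir)
  idx <- as.integer(sub(paste0("^", prefix, "([0-9]+)\\.tiff?$"), "\\1",
                        basename(files)))
  if (anyNA(idx)) stop("could not parse frame index from filenames")
  files <- files[order(idx)]
  lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
}

#' Write an image sequence as 32-bit float TIFFs
#'
#' Values are clipped to \[0, 1\] (float TIFF storage outside that range
#' is undefined in the underlying library).
#'
#' @param frames list of numeric matrices.
#' @param dir output directory.
#' @param prefix filename prefix, default `"t"`.
#' @export
write_image_sequence <- function(frames, dir, prefix = "t") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- pad_width(length(frames))
  for (t in seq_along(frames)) {
    f <- file.path(dir, sprintf("%s%0*d.tif", prefix, w, t - 1L))
    # 32 bits per sample selects IEEE float storage
    tiff::writeTIFF(pmin(pmax(frames[[t]], 0), 1), f,
                    bits.per.sample = 32L, compression = "none")
  }
  invisible(dir)
}

#' Read an image sequence
#'
#' @param dir directory with `<prefix><T>.tif` files.
#' @param prefix filename prefix, default `"t"`.
#' @return list of numeric matrices ordered by frame index.
#' @export
read_image_sequence <- function(dir, prefix = "t") {
  files <- list.files(dir, pattern = paste0("^", prefix, "[0-9]+\\.tiff?$"),
                      full.names = TRUE)
  if (!length(files)) stop("no ", prefix, "*.tif files in ", dir)
  idx <- as.integer(sub(paste0("^", prefix, "([0-9]+)\\.tiff?$"), "\\1",
                        basename(files)))
  files <- files[order(idx)]
  lapply(files, function(f) tiff::readTIFF(f))
}

#' SEG measure (Jaccard-based pixel score)
#'
#' For every ground-truth object, a result object is a match iff it
#' covers strictly more than half of the ground-truth pixels (at most one
#' can). SEG is the mean, over all ground-truth objects across all
#' frames, of the Jaccard index `|GT n R| / |GT u R|` with unmatched
#' objects contributing 0.
#'
#' @param gt_frames,result_frames aligned lists of label images (single
#'   images are accepted).
#' @return score in \[0, 1\] (`NaN` if the ground truth has no objects).
#' @export
seg_measure <- function(gt_frames, result_frames) {
  if (!is.list(gt_frames)) gt_frames <- list(gt_frames)
  if (!is.list(result_frames)) result_frames <- list(result_frames)
  if (length(gt_frames) != length(result_frames)) {
    stop("sequences must have equal length")
  }
  scores <- numeric(0)
  for (t in seq_along(gt_frames)) {
    gt <- gt_frames[[t]]
    res <- result_frames[[t]]
    if (!identical(dim(gt), dim(res))) stop("frame shape mismatch")
    for (id in label_ids(gt)) {
      gpix <- gt == id
      ng <- sum(gpix)
      over <- res[gpix]
      over <- over[over > 0]
      s <- 0
      if (length(over)) {
        tab <- table(over)
        best <- which.max(tab)
        inter <- as.integer(tab[best])
        if (inter > 0.5 * ng) {
          rid <- as.integer(names(tab)[best])
          union <- ng + sum(res == rid) - inter
          s <- inter / union
        }
      }
      scores <- c(scores, s)
    }
  }
  mean(scores)
}

#' Overall performance measures
#'
#' Combined Cell Segmentation / Cell Tracking Benchmark scores,
#' `OP_CSB = 0.5 * (DET + SEG)` and `OP_CTB = 0.5 * (SEG + TRA)`.
#' DET and TRA are graph-matching measures computed by the official
#' challenge tool; they are taken as inputs here.
#'
#' @param seg,det,tra component scores in \[0, 1\].
#' @return named numeric vector with `OP_CSB` and/or `OP_CTB`.
#' @export
op_measures <- function(seg, det = NULL, tra = NULL) {
  out <- c()
  if (!is.null(det)) out <- c(out, OP_CSB = 0.5 * (det + seg))
  if (!is.null(tra)) out <- c(out, OP_CTB = 0.5 * (seg + tra))
  out
}

#' Replace empty frames by the temporally closest result
#'
#' Frames without any labeled object are replaced by the nearest
#' non-empty frame's result; the earlier frame wins ties.
#'
#' @param frames list of label images.
#' @return list with empty frames filled in.
#' @export
fill_empty_frames <- function(frames) {
  nonempty <- which(vapply(frames, function(f) any(f > 0), logical(1)))
  if (!length(nonempty)) {
    warning("all frames empty; nothing to fill")
    return(frames)
  }
  for (t in seq_along(frames)) {
    if (t %in% nonempty) next
    dist <- abs(nonempty - t)
    src <- nonempty[which.min(dist)]  # which.min takes the first minimum,
    frames[[t]] <- frames[[src]]      # so earlier frames win ties
  }
  frames
}
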