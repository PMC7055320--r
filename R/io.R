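#' Read and write track and interval files
#'
#' Count tracks are tab-separated `chrom`, `pos` (0-based), `c_count`,
#' `t_count`. Methylation tracks are bedGraph (`chrom`, `start`,
#' `end = start + 1`, `methylation`). DMR sets and planted truth are BED6+
#' (name carries the DMR id or planted lineage; score is the detector peak
#' score capped and rescaled to 0-1000).
#'
#' @param track,dmrs,truth Tibbles as produced by the package.
#' @param path File path.
#' @param score_cap Peak score mapped to BED score 1000 (default 100).
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name track_io
NULL

#' @rdname track_io
#' @export
write_count_track <- function(track, path) {
  stopifnot_cols(track, c("chrom", "pos", "c_count", "t_count"))
  readr::write_tsv(track[, c("chrom", "pos", "c_count", "t_count")], path)
  invisible(path)
}

#' @rdname track_io
#' @export
read_count_track <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    c_count = readr::col_integer(), t_count = readr::col_integer()
  ))
}

#' @rdname track_io
#' @export
write_bedgraph <- function(track, path) {
  stopifnot_cols(track, c("chrom", "pos", "methylation"))
  bg <- tibble(chrom = track$chrom, start = track$pos,
               end = track$pos + 1L, value = track$methylation)
  readr::write_tsv(bg, path, col_names = FALSE)
  invisible(path)
}

#' @rdname track_io
#' @export
read_bedgraph <- function(path) {
  bg <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid")
  tibble(chrom = bg$chrom, pos = bg$start, methylation = bg$value)
}

#' @rdname track_io
#' @export
write_dmr_bed <- function(dmrs, path, score_cap = 100) {
  stopifnot_cols(dmrs, c("chrom", "start", "end"))
  n <- nrow(dmrs)
  score <- if ("q_max" %in% names(dmrs)) {
    as.integer(round(clamp(dmrs$q_max, 0, score_cap) / score_cap * 1000))
  } else rep(0L, n)
  name <- paste0("DMR", seq_len(n))
  if ("lineage" %in% names(dmrs)) {
    name <- paste0(name, "|", dmrs$lineage %||% "")
  }
  extra <- dmrs[, intersect(c("n_cpgs", "direction"), names(dmrs)),
                drop = FALSE]
  bed <- dplyr::bind_cols(
    tibble(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
           name = name, score = score, strand = "."),
    extra
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname track_io
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot_cols(truth, c("chrom", "start", "end", "lineage", "direction"))
  bed <- tibble(chrom = truth$chrom, start = truth$start, end = truth$end,
                name = paste0(truth$lineage, "_", truth$direction),
                score = 0L, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname track_io
#' @export
read_dmr_bed <- function(path) {
  cols <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols())
  out <- tibble(chrom = as.character(cols$X1), start = as.integer(cols$X2),
                end = as.integer(cols$X3))
  if (ncol(cols) >= 4) out$name <- as.character(cols$X4)
  if (ncol(cols) >= 7) out$n_cpgs <- as.integer(cols$X7)
  if (ncol(cols) >= 8) out$direction <- as.character(cols$X8)
  out
}
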