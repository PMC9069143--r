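#' Acquisition protocols
#'
#' A protocol is a tibble with one row per acquired volume and columns
#' `b_value` (s/mm^2), `shape` (`"LTE"` or `"STE"`), `dir_x`, `dir_y`, `dir_z`
#' (unit encoding direction for LTE, `NA` for STE, which is rotationally
#' invariant by construction and acquired as exact repeats) and `repetition`
#' (1-based index within each `(b_value, shape)` group). Repetition time and
#' echo time are carried as attributes `tr_ms` and `te_ms`.
#'
#' @param entries data frame with the columns above (missing `repetition` is
#'   filled in).
#' @param tr_ms repetition time in ms (> 0).
#' @param te_ms echo time in ms (>= 0).
#' @return a `dwi_protocol` tibble.
#' @export
dwi_protocol <- function(entries, tr_ms, te_ms) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1)
  stopifnot(tr_ms > 0, te_ms >= 0)
  entries <- tibble::as_tibble(entries)
  req <- c("b_value", "shape", "dir_x", "dir_y", "dir_z")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0) {
    stop("protocol entries lack columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(entries$shape %in% c("LTE", "STE"))) {
    stop("shape must be 'LTE' or 'STE'", call. = FALSE)
  }
  if (any(entries$b_value < 0)) stop("b-values must be non-negative", call. = FALSE)
  is_lte <- entries$shape == "LTE"
  d <- as.matrix(entries[, c("dir_x", "dir_y", "dir_z")])
  if (any(is_lte)) {
    nrm <- sqrt(rowSums(d[is_lte, , drop = FALSE]^2))
    if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-9)) {
      stop("LTE directions must be unit vectors", call. = FALSE)
    }
  }
  entries[!is_lte, c("dir_x", "dir_y", "dir_z")] <- NA_real_
  if (!"repetition" %in% names(entries)) {
    entries <- entries |>
      dplyr::group_by(.data$b_value, .data$shape) |>
      dplyr::mutate(repetition = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  entries <- entries[, c(req, "repetition")]
  structure(entries,
    tr_ms = tr_ms, te_ms = te_ms,
    class = c("dwi_protocol", class(tibble::tibble()))
  )
}

#' @rdname dwi_protocol
#' @param protocol a `dwi_protocol`.
#' @export
protocol_tr <- function(protocol) attr(protocol, "tr_ms")

#' @rdname dwi_protocol
#' @export
protocol_te <- function(protocol) attr(protocol, "te_ms")

#' The default clinical tensor-valued acquisition protocol
#'
#' The protocol this package models throughout: b-values of 100, 700, 1,400
#' and 2,000 s/mm^2, acquired with LTE in 3, 3, 6 and 6 directions and with
#' STE repeated 6, 6, 11 and 16 times respectively (57 volumes in total), at
#' TR 5,000 ms and TE 84 ms. The 3-direction LTE set is the coordinate axes;
#' the 6-direction set is the antipodally reduced icosahedron
#' ([scheme_icosa6()]).
#'
#' @return a `dwi_protocol` with 57 rows.
#' @export
study_protocol <- function() {
  bvals <- c(100, 700, 1400, 2000)
  lte_n <- c(3, 3, 6, 6)
  ste_n <- c(6, 6, 11, 16)
  rows <- list()
  for (i in seq_along(bvals)) {
    dirs <- if (lte_n[i] == 3) scheme_axes3() else scheme_icosa6()
    rows[[length(rows) + 1]] <- tibble::tibble(
      b_value = bvals[i], shape = "LTE",
      dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
      repetition = seq_len(lte_n[i])
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      b_value = bvals[i], shape = "STE",
      dir_x = NA_real_, dir_y = NA_real_, dir_z = NA_real_,
      repetition = seq_len(ste_n[i])
    )
  }
  dwi_protocol(dplyr::bind_rows(rows), tr_ms = 5000, te_ms = 84)
}

#' Select protocol entries by b-value and/or shape
#'
#' @param protocol a `dwi_protocol`.
#' @param b optional b-value filter (s/mm^2).
#' @param shape optional `"LTE"` or `"STE"` filter.
#' @return a `dwi_protocol` with the matching rows (possibly zero rows) and
#'   the same TR/TE.
#' @export
protocol_subset <- function(protocol, b = NULL, shape = NULL) {
  keep <- rep(TRUE, nrow(protocol))
  if (!is.null(b)) keep <- keep & protocol$b_value == b
  if (!is.null(shape)) keep <- keep & protocol$shape == shape
  out <- tibble::as_tibble(protocol)[keep, , drop = FALSE]
  structure(out,
    tr_ms = protocol_tr(protocol), te_ms = protocol_te(protocol),
    class = class(protocol)
  )
}

#' Scan time of a protocol or protocol subset
#'
#' Each volume occupies one repetition time, so the scan time of a selection
#' is `(number of selected entries) * TR`, reported in seconds. An empty
#' selection takes 0 s.
#'
#' @inheritParams protocol_subset
#' @return scan time in seconds.
#' @examples
#' scan_time(study_protocol(), b = 2000, shape = "LTE") # 30 s
#' scan_time(study_protocol(), b = 2000, shape = "STE") # 80 s
#' @export
scan_time <- function(protocol, b = NULL, shape = NULL) {
  sel <- protocol_subset(protocol, b = b, shape = shape)
  nrow(sel) * protocol_tr(protocol) / 1000
}

#' B-tensor for one protocol entry
#' @param entry one-row data frame with `b_value`, `shape`, `dir_*`.
#' @return a `"btensor"`.
#' @export
entry_btensor <- function(entry) {
  if (entry$shape[1] == "STE") {
    make_ste_btensor(entry$b_value[1])
  } else {
    make_lte_btensor(entry$b_value[1], c(entry$dir_x[1], entry$dir_y[1], entry$dir_z[1]))
  }
}

#' Read and write acquisition tables
#'
#' The on-disk protocol format is a tab-separated table with a header and one
#' row per volume, columns `b_value`, `shape`, `dir_x`, `dir_y`, `dir_z`,
#' `repetition` (in that order; STE rows have `NA` directions), plus `tr_ms`
#' and `te_ms` repeated on every row so the file is self-contained.
#' `write_bval_bvec()` additionally writes FSL-style `.bval`/`.bvec`
#' companions for LTE-compatible consumers; STE volumes get a zero direction
#' vector there, and the bvec is in image coordinates.
#'
#' @param protocol a `dwi_protocol`.
#' @param path file path for the TSV table.
#' @return `read_protocol()` returns a `dwi_protocol`; writers return the
#'   path(s), invisibly.
#' @export
write_protocol <- function(protocol, path) {
  out <- tibble::as_tibble(protocol)
  out$tr_ms <- protocol_tr(protocol)
  out$te_ms <- protocol_te(protocol)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  dwi_protocol(tab[, c("b_value", "shape", "dir_x", "dir_y", "dir_z", "repetition")],
    tr_ms = tab$tr_ms[1], te_ms = tab$te_ms[1]
  )
}

#' @rdname write_protocol
#' @param prefix path prefix; `.bval` and `.bvec` are appended.
#' @export
write_bval_bvec <- function(protocol, prefix) {
  b <- protocol$b_value
  d <- t(as.matrix(tibble::as_tibble(protocol)[, c("dir_x", "dir_y", "dir_z")]))
  d[is.na(d)] <- 0
  writeLines(paste(format(b, trim = TRUE, scientific = FALSE), collapse = " "),
    paste0(prefix, ".bval")
  )
  writeLines(apply(d, 1, function(r) paste(format(r, trim = TRUE), collapse = " ")),
    paste0(prefix, ".bvec")
  )
  invisible(paste0(prefix, c(".bval", ".bvec")))
}
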