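#' Parcellation metadata
#'
#' Constructs and validates the parcellation metadata table: one row per
#' cortical parcel with its identifier, hemisphere, functional network label
#' and spherical centroid.  The centroids are the substrate for the
#' spin-permutation spatial null model, so they must be unit vectors.
#'
#' @param df A data.frame with columns `parcel_id` (integers `1..P`,
#'   contiguous), `hemisphere` (`"L"`/`"R"`), `network` (one label per
#'   parcel), and centroid coordinates `x`, `y`, `z` (unit norm within 1e-9).
#'
#' @return The validated table with class `parcellation_meta`.  Row order is
#'   authoritative: all matrices in the package are indexed in metadata file
#'   order.
#' @export
parcellation_meta <- function(df) {
  df <- as.data.frame(df)
  need <- c("parcel_id", "hemisphere", "network", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_axisflux("parcellation metadata missing column(s): %s",
                  paste(miss, collapse = ", "))
  }
  p <- nrow(df)
  ids <- as.integer(df$parcel_id)
  if (anyDuplicated(ids) || !setequal(ids, seq_len(p))) {
    stop_axisflux("parcel_id must be unique and contiguous 1..%d", p)
  }
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop_axisflux("hemisphere must be 'L' or 'R'")
  }
  if (anyNA(df$network) || any(!nzchar(as.character(df$network)))) {
    stop_axisflux("every parcel needs exactly one network label")
  }
  nrm <- sqrt(df$x^2 + df$y^2 + df$z^2)
  bad <- which(abs(nrm - 1) > 1e-9)
  if (length(bad)) {
    stop_axisflux("centroid not unit norm at parcel_id %s",
                  paste(ids[bad], collapse = ", "))
  }
  df$parcel_id <- ids
  df$hemisphere <- as.character(df$hemisphere)
  df$network <- as.character(df$network)
  class(df) <- c("parcellation_meta", "data.frame")
  df
}

#' @export
print.parcellation_meta <- function(x, ...) {
  cat(sprintf("parcellation_meta: %d parcels (%d L / %d R), %d networks\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              length(unique(x$network))))
  invisible(x)
}

#' Read / write parcellation metadata
#'
#' CSV with columns `parcel_id, hemisphere, network, x, y, z`.
#'
#' @param path File path.
#' @return `read_parcellation()` returns a validated [parcellation_meta()].
#' @export
read_parcellation <- function(path) {
  parcellation_meta(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param meta A [parcellation_meta()] table.
#' @rdname read_parcellation
#' @export
write_parcellation <- function(meta, path) {
  df <- as.data.frame(meta)
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  df$z <- sprintf("%.17g", df$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
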