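#' @keywords internal
"_PACKAGE"

## Canonical seven-network order used everywhere a fixed network ordering is
## needed (dispersion pair naming, heatmap-style outputs).
AXISFLUX_NETWORKS <- c(
  "visual", "somatomotor", "dorsal_attention", "ventral_attention",
  "limbic", "frontoparietal", "default_mode"
)

#' Canonical functional network names
#'
#' Returns the fixed seven-network naming and ordering used by the package
#' (visual, somatomotor, dorsal attention, ventral attention, limbic,
#' frontoparietal, default mode).  Dispersion outputs and pair labels always
#' follow this order.
#'
#' @return Character vector of length 7.
#' @export
network_names <- function() AXISFLUX_NETWORKS

## Deterministic substream seed: a stable string hash mixed with the global
## seed, so adding a new generator never perturbs the streams of others.
## Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

stop_axisflux <- function(...) stop(sprintf(...), call. = FALSE)

## Ordering of network levels actually present in a metadata table: canonical
## names first (in canonical order), any extra labels after, alphabetically.
network_levels <- function(labels) {
  u <- unique(as.character(labels))
  c(AXISFLUX_NETWORKS[AXISFLUX_NETWORKS %in% u],
    sort(setdiff(u, AXISFLUX_NETWORKS)))
}

## Benjamini-Hochberg adjusted q-values; thin wrapper kept for a single
## documented multiple-testing policy across modules.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

## Column z-scoring with an informative error on constant columns.
zscore_columns <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    stop_axisflux("constant covariate(s): %s",
                  paste(colnames(x)[sds == 0 | is.na(sds)], collapse = ", "))
  }
  scale(x)[, , drop = FALSE]
}
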