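## Classifier persistence: a binary parameter container plus a JSON
## sidecar describing shapes and provenance.

#' Save a trained classifier
#'
#' Writes `params.rds` (the parameter list) and `model.json` (shapes,
#' dimensions, seed-free metadata) into `dir`.
#'
#' @param params a `ksmo_classifier`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(params, dir) {
  stopifnot(inherits(params, "ksmo_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(unclass(params), file.path(dir, "params.rds"))
  meta <- list(d = params$d, d_b = params$d_b, hidden = params$hidden,
               dropout_p = params$dropout_p,
               shapes = lapply(params[.param_names], function(p) {
                 if (is.matrix(p)) dim(p) else length(p)
               }))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a classifier saved by [save_classifier()]
#' @param dir directory given to [save_classifier()].
#' @return A `ksmo_classifier`.
#' @export
load_classifier <- function(dir) {
  params <- readRDS(file.path(dir, "params.rds"))
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  stopifnot(params$d == meta$d, params$d_b == meta$d_b)
  structure(params, class = "ksmo_classifier")
}
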