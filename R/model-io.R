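#' Read and write ladder-model configuration files
#'
#' Models are stored as JSON documents with fields `name`, `n_steps` and
#' `transitions`, the latter an array of
#' `{edge, k_forward, k_backward, ligand_dependent}` records. Units are
#' fixed: 1/(uM s) for the forward (association) rate of ligand-dependent
#' edges and 1/s for everything else. Numbers are serialized at full
#' precision, so a write/read round trip reproduces the model bit for bit.
#'
#' @param model A `ladder_model`.
#' @param path File path of the JSON document.
#' @return `read_ladder_model()` returns a validated `ladder_model`;
#'   `write_ladder_model()` returns `path` invisibly.
#' @export
write_ladder_model <- function(model, path) {
  stopifnot(inherits(model, "ladder_model"))
  doc <- list(
    name = model$name,
    n_steps = model$n_steps,
    transitions = model$transitions[, c("edge", "k_forward", "k_backward",
                                        "ligand_dependent")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_ladder_model
#' @param balance_tol Passed on to [build_ladder_model()].
#' @export
read_ladder_model <- function(path, balance_tol = 1e-6) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path))
  }
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(doc$n_steps) || is.null(doc$transitions)) {
    abort(sprintf("`%s` is not a ladder-model config (needs n_steps, transitions).", path))
  }
  build_ladder_model(
    n_steps = doc$n_steps,
    rates = as_tibble(doc$transitions)[, c("edge", "k_forward", "k_backward")],
    name = doc$name %||% "unnamed",
    balance_tol = balance_tol
  )
}
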