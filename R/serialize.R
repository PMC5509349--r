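#' Write a metaplastic model to a JSON document
#'
#' Serializes the model (family, state count, parameters, efficacies, and
#' both full matrices) at full floating-point precision so that
#' [read_model()] round-trips bit-exactly.
#'
#' @param model A `metaplastic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "metaplastr-model/1",
    family = model$family,
    n_states = model$n_states,
    params = as.numeric(model$params),
    param_names = names(model$params) %||% character(0),
    efficacies = model$efficacies,
    # matrices flattened column-major for an unambiguous round trip
    potentiation = as.numeric(model$potentiation),
    depression = as.numeric(model$depression)
  )
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a metaplastic model written by [write_model()]
#'
#' @param path File path.
#' @return A validated `metaplastic_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "metaplastr-model/1")) {
    stop("not a metaplastr model file: ", path, call. = FALSE)
  }
  n <- as.integer(doc$n_states)
  params <- as.numeric(doc$params)
  if (length(doc$param_names) == length(params)) {
    names(params) <- doc$param_names
  }
  m <- new_metaplastic_model(
    n,
    matrix(as.numeric(doc$potentiation), n, n),
    matrix(as.numeric(doc$depression), n, n),
    as.numeric(doc$efficacies),
    doc$family,
    params
  )
  bad <- validate_model(m)
  if (length(bad) > 0) {
    stop("invalid model in ", path, ": ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  m
}
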