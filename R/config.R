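#' Read a notegate YAML configuration
#'
#' A single YAML file can carry any of the sections `confidence`, `penalty`,
#' `gate`, `synth` and `mock`; each section's keys are passed to the
#' corresponding constructor ([confidence_config()], [penalty_config()],
#' [gate_config()], [synth_config()], [mock_profile()]), so defaults apply
#' for anything omitted. Unknown keys in a section are an error, to catch
#' typos early.
#'
#' @param path Path to a YAML file (missing file or `NULL` gives all
#'   defaults).
#' @return List with elements `confidence`, `penalty`, `gate`, `synth`,
#'   `mock`.
#' @export
read_notegate_config <- function(path = NULL) {
  raw <- if (!is.null(path) && file.exists(path)) {
    yaml::read_yaml(path)
  } else {
    list()
  }
  build <- function(section, constructor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    known <- names(formals(constructor))
    unknown <- setdiff(names(args), known)
    if (length(unknown) > 0L) {
      stop(
        "unknown key(s) in config section '", section, "': ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    do.call(constructor, args)
  }
  mock <- build("mock", mock_profile)
  synth_args <- raw[["synth"]]
  if (is.null(synth_args)) synth_args <- list()
  synth_args$mock <- mock
  known <- names(formals(synth_config))
  unknown <- setdiff(names(synth_args), known)
  if (length(unknown) > 0L) {
    stop("unknown key(s) in config section 'synth': ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  list(
    confidence = build("confidence", confidence_config),
    penalty = build("penalty", penalty_config),
    gate = build("gate", gate_config),
    synth = do.call(synth_config, synth_args),
    mock = mock
  )
}
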