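## Strict run-configuration parsing for the command-line tool.

RUNCONFIG_KEYS <- c("schema", "schema_config", "context_base_uri",
                    "context_terms", "linking_property", "mode",
                    "input", "input2", "output", "ground_truth",
                    "seed", "log_level")

#' Read a run configuration (strict)
#'
#' YAML/JSON mapping with keys: `schema` ("provenir", "demo" or "bkr"),
#' `schema_config` (extension config path), `context_base_uri`,
#' `context_terms`, `linking_property`, `mode`, `input`, `input2`,
#' `output`, `ground_truth`, `seed`, `log_level`. Unknown keys are
#' rejected.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
readRunConfig <- function(path) {
  cfg <- read_config_file(path)
  unknown <- setdiff(names(cfg), RUNCONFIG_KEYS)
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Resolve a named built-in schema
#'
#' @param name "provenir" (the upper-level schema), "demo" (the
#'   parasite-experiment extension) or "bkr" (the knowledge-repository
#'   extension).
#' @return an [OntologySchema-class].
#' @export
namedSchema <- function(name = c("provenir", "demo", "bkr")) {
  name <- match.arg(name)
  switch(name, provenir = defaultProvenirSchema(),
         demo = demoExtensionSchema(), bkr = bkrExtensionSchema())
}
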