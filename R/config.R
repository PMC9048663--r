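#' Tool configuration
#'
#' Bundles the local record cache location, offline policy, solver tolerance,
#' log destination and default compartment used when converting database
#' records. Record retrieval is abstracted behind a *provider* function
#' `function(source, identifier, kind) -> raw text or NULL`; the default
#' provider is `NULL`, i.e. strictly cache/fixture based, which keeps every
#' workflow reproducible without network access. [fixture_provider()] builds
#' a provider from an in-memory record set such as the output of
#' [generate_fixture_records()].
#'
#' @param cache_dir directory for cached raw records (created on first use),
#'   laid out as `<cache_dir>/<source>/<kind>/<identifier>.<ext>`.
#' @param offline when `TRUE`, a cache miss is an error rather than a
#'   provider call.
#' @param solver_tolerance strictly positive flux tolerance used by the
#'   non-zero flux test.
#' @param log_path default curation log file.
#' @param default_compartment compartment tag assigned to imported entities.
#' @param provider optional retrieval function (see above).
#' @return A `tool_config` object. Fetch statistics (cache hits/misses,
#'   provider calls) accumulate in `config$stats`.
#' @export
tool_config <- function(cache_dir = file.path(tempdir(), "pathcurator_cache"),
                        offline = TRUE,
                        solver_tolerance = 1e-7,
                        log_path = file.path(tempdir(), "pathcurator.log"),
                        default_compartment = "c",
                        provider = NULL) {
  stopifnot(is.numeric(solver_tolerance), solver_tolerance > 0)
  structure(list(cache_dir = cache_dir, offline = isTRUE(offline),
                 solver_tolerance = solver_tolerance, log_path = log_path,
                 default_compartment = default_compartment,
                 provider = provider,
                 stats = new.env(parent = emptyenv())),
            class = "tool_config")
}

#' @rdname tool_config
#' @param records nested list `records[[source]][[kind]][[identifier]]` of
#'   raw record texts.
#' @export
fixture_provider <- function(records) {
  force(records)
  function(source, identifier, kind) {
    txt <- records[[source]][[kind]][[identifier]]
    if (is.null(txt)) NULL else txt
  }
}

.bump <- function(config, what) {
  cur <- get0(what, envir = config$stats, ifnotfound = 0L)
  assign(what, cur + 1L, envir = config$stats)
  invisible(NULL)
}
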