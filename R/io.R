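#' Read a delimited numeric matrix
#'
#' Reads a rectangular numeric table from UTF-8 delimited text ('.' decimal
#' separator). Ragged rows and non-numeric cells are rejected with a
#' diagnostic naming the offending line and column.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default comma).
#' @param header Logical; if \code{TRUE} the first row holds column names.
#' @return A numeric matrix; column names are attached when
#'   \code{header = TRUE}.
#' @export
read_matrix <- function(path, delimiter = ",", header = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  col_names <- NULL
  first_body <- 1L
  if (header) {
    col_names <- trimws(cells[[1L]])
    first_body <- 2L
    if (length(cells) < 2L) {
      stop(sprintf("no data rows below the header in %s", path),
           call. = FALSE)
    }
  }
  body <- cells[first_body:length(cells)]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad + first_body - 1L, widths[bad], widths[1L]),
         call. = FALSE)
  }
  vals <- suppressWarnings(lapply(body, function(r) as.numeric(trimws(r))))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1L]
      stop(sprintf("non-numeric cell in %s: line %d, column %d ('%s')",
                   path, i + first_body - 1L, j, trimws(body[[i]][j])),
           call. = FALSE)
    }
  }
  M <- do.call(rbind, vals)
  if (!is.null(col_names)) colnames(M) <- col_names
  M
}

#' Write a numeric matrix as delimited text
#'
#' Values are written with 15 significant digits, so a write/read round
#' trip reproduces the matrix to near machine precision.
#'
#' @param M A numeric matrix (a vector is written as one row).
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @param digits Significant digits to keep.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(M, path, delimiter = ",", digits = 15) {
  if (is.vector(M)) M <- matrix(M, nrow = 1L)
  txt <- apply(M, 1L, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = delimiter)
  })
  if (!is.null(colnames(M))) {
    txt <- c(paste(colnames(M), collapse = delimiter), txt)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run that writes artifacts records exactly one manifest
#' next to them: the command, its arguments, the root seed, a digest of the
#' config, the artifact paths and the package version. This makes any
#' output directory self-describing and reproducible.
#'
#' @param out_dir Output directory.
#' @param command Command or function name that produced the artifacts.
#' @param args Named list of arguments (must be JSON-representable).
#' @param seed Root seed used for all randomness in the run.
#' @param artifacts Character vector of artifact file names.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, args = list(), seed = NULL,
                           artifacts = character()) {
  manifest <- list(
    command = command,
    args = args,
    config_digest = digest_config(args),
    seed = seed,
    artifacts = as.list(artifacts),
    package_version = as.character(utils::packageVersion("kerneltransfer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# order-independent digest of a config list; no external digest package is
# needed at this fidelity
digest_config <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("sum%08x-len%d", sum(utf8ToInt(as.character(s))), nchar(s))
}

validate_config <- function(config, schema) {
  problems <- character()
  for (field in names(schema)) {
    spec <- schema[[field]]
    val <- config[[field]]
    if (is.null(val)) {
      if (isTRUE(spec$required)) {
        problems <- c(problems, sprintf("missing required field '%s'", field))
      }
      next
    }
    if (!is.null(spec$type) && !type_ok(val, spec$type)) {
      problems <- c(problems,
                    sprintf("field '%s' must be of type %s", field,
                            spec$type))
    }
    if (!is.null(spec$one_of) && !val %in% spec$one_of) {
      problems <- c(problems,
                    sprintf("field '%s' must be one of: %s", field,
                            paste(spec$one_of, collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop(paste(c("invalid config:", paste(" -", problems)), collapse = "\n"),
         call. = FALSE)
  }
  invisible(config)
}

type_ok <- function(x, cls) {
  switch(cls, numeric = is.numeric(x), character = is.character(x),
         list = is.list(x), logical = is.logical(x), inherits(x, cls))
}

#' Run a configured analysis pipeline
#'
#' Executes one of the package's end-to-end analyses from a single config
#' (a named list, or a path to a JSON file with the same structure) and
#' writes its artifacts plus a run manifest to \code{out_dir}. Supported
#' \code{kind}s:
#' \describe{
#'   \item{theory}{closed-form versus Monte-Carlo risk over the verification
#'     grid; writes \code{theory_table.csv} with columns for the grid
#'     coordinates, closed form, Monte-Carlo mean/SE and z-score. Config
#'     fields: \code{estimator}, \code{trials}.}
#'   \item{classes}{the clustered-classification transfer benchmark; writes
#'     \code{metrics.json} with projected and baseline accuracy. Config
#'     fields: \code{n_t} and any [gen_clustered_classification()]
#'     override.}
#'   \item{drugscreen}{the drug-screen transfer benchmark; writes
#'     \code{metrics.csv} with per-model, per-stratum screening metrics.
#'     Config fields: \code{n_target_train}, \code{sim} (overrides for
#'     [drug_screen_sim()]).}
#' }
#' Runs are deterministic given config and seed.
#'
#' @param config Named list or path to a JSON config file. Must contain a
#'   \code{kind} field.
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed for all randomness in the run.
#' @return The config-dependent result object, invisibly; artifacts and
#'   \code{manifest.json} are written to \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config, list(
    kind = list(required = TRUE, type = "character",
                one_of = c("theory", "classes", "drugscreen"))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(config$kind,
    theory = {
      validate_config(config, list(
        estimator = list(type = "character",
                         one_of = c("projected", "translated")),
        trials = list(type = "numeric")))
      tab <- theory_closure_grid(
        estimator = config$estimator %||% "projected",
        trials = as.integer(config$trials %||% 2000L), seed = seed)
      utils::write.csv(tab, file.path(out_dir, "theory_table.csv"),
                       row.names = FALSE)
      artifacts <- "theory_table.csv"
      tab
    },
    classes = {
      validate_config(config, list(n_t = list(type = "numeric")))
      extra <- config[setdiff(names(config), c("kind", "n_t"))]
      res <- do.call(classification_transfer_benchmark,
                     c(list(seed = seed, n_t = config$n_t %||% 50), extra))
      jsonlite::write_json(res, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- "metrics.json"
      res
    },
    drugscreen = {
      validate_config(config, list(n_target_train = list(type = "numeric"),
                                   sim = list(type = "list")))
      res <- drug_screen_benchmark(
        seed = seed,
        n_target_train = config$n_target_train %||% 40,
        sim_args = as.list(config$sim %||% list()))
      utils::write.csv(res, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
      artifacts <- "metrics.csv"
      res
    })
  write_manifest(out_dir, command = paste0("run_pipeline:", config$kind),
                 args = config, seed = seed, artifacts = artifacts)
  invisible(result)
}
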