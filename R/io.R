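#' Name a designed sequence
#'
#' The name records the requested length, the achieved mean disorder score
#' (two decimals), and the rank of the design within its request, in the
#' template `"{l}-{mean}_{rank}"`, e.g. `"100-0.60_1"`.
#'
#' @param l Requested length.
#' @param achieved_mean Mean disorder score of the design.
#' @param rank Rank within the request (>= 1).
#' @return Name string.
#' @export
name_sequence <- function(l, achieved_mean, rank) {
  stopifnot(rank >= 1L)
  sprintf("%d-%.2f_%d", as.integer(l), achieved_mean, as.integer(rank))
}

#' @rdname name_sequence
#' @param name A name produced by `name_sequence()`.
#' @return `parse_sequence_name` returns a list with `l`, `mean` (two-decimal
#'   score) and `rank`.
#' @export
parse_sequence_name <- function(name) {
  m <- regmatches(name,
                  regexec("^([0-9]+)-([0-9]+\\.[0-9]{2})_([0-9]+)$", name))[[1L]]
  if (length(m) != 4L)
    stop("not a valid sequence name: ", name, call. = FALSE)
  list(l = as.integer(m[2L]), mean = as.numeric(m[3L]),
       rank = as.integer(m[4L]))
}

#' Write sequences to FASTA
#'
#' Standard FASTA with 60-column line wrapping; record headers are the
#' sequence names. Accepts a named character vector or a list of
#' `designed_sequence` objects (their `name` fields become the headers).
#'
#' @param records Named character vector, or list of `designed_sequence`s.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records) &&
      all(vapply(records, inherits, logical(1), "designed_sequence")))
    records <- stats::setNames(
      vapply(records, `[[`, character(1), "sequence"),
      vapply(records, `[[`, character(1), "name"))
  stopifnot(is.character(records), length(records) >= 1L,
            !is.null(names(records)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(records), path,
                              width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), names(aas))
}

#' Write design provenance as JSON lines
#'
#' One JSON object per design: name, requested target, achieved statistics,
#' and the full provenance record (seed, initial and inserted blocks,
#' per-insertion rejection counts, discarded-sequence count). Together with
#' the scorer parameters this is sufficient to replay every design
#' ([replay_design()]).
#'
#' @param designs List of `designed_sequence` objects.
#' @param path Output path (`.jsonl`).
#' @export
write_provenance <- function(designs, path) {
  lines <- vapply(designs, function(d)
    jsonlite::toJSON(list(
      name = d$name, sequence = d$sequence,
      requested_dt = d$requested_dt,
      achieved_mean = d$achieved_mean, achieved_delta = d$achieved_delta,
      final_mean = d$final_mean, final_delta = d$final_delta,
      provenance = d$provenance), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks a design request against the user-facing bounds before any work is
#' done: length within 50-200 residues, 1-10 sequences per request, and a
#' target disorder probability on the 0.55-0.95 grid.
#'
#' @param config List with at least `l`, `dt`, `n`, and optionally `seed`,
#'   `add_tryptophan`.
#' @param params [design_params()].
#' @return The validated config (with defaults filled in), invisibly usable
#'   downstream; errors name the violated bound.
#' @export
validate_run_config <- function(config, params = design_params()) {
  l <- as.integer(config$l)
  if (length(l) != 1L || is.na(l) || l < params$length_min ||
      l > params$length_max)
    stop("sequence length must lie between ", params$length_min,
         " (minimum) and ", params$length_max, " (maximum) residues",
         call. = FALSE)
  n <- as.integer(if (is.null(config$n)) 1L else config$n)
  if (is.na(n) || n < params$n_min || n > params$n_max)
    stop("number of sequences must lie between ", params$n_min,
         " (minimum) and ", params$n_max, " (maximum)", call. = FALSE)
  dt <- check_dt(as.numeric(config$dt), params)
  list(l = l, n = n, dt = dt,
       seed = as.integer(if (is.null(config$seed)) 1L else config$seed),
       add_tryptophan = isTRUE(config$add_tryptophan))
}

#' @rdname validate_run_config
#' @param path Path to a YAML run-configuration file with the same keys.
#' @export
read_run_config <- function(path, params = design_params()) {
  validate_run_config(yaml::read_yaml(path), params)
}
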