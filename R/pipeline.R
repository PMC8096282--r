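#' Run configuration
#'
#' Bundles the thresholds of the method with file paths and a seed. The
#' defaults are the method's canonical constants: pattern significance
#' `alpha = 0.05` with the top-2 rule, fair/poor penalty boundary 1, loop
#' regions padded by 4 nt, posterior cutoff 0.5, and priors
#' (0.549, 0.451).
#'
#' @param guidance,candidates,shape,patterns,model Input file paths
#'   (dot-bracket/CT structures, SHAPE profile, pattern TSV, model JSON).
#' @param out_dir Output directory.
#' @param alpha,top_k Pattern-discovery thresholds.
#' @param fair_threshold,region_pad,posterior_cutoff Refinement thresholds.
#' @param prior_true Prior probability of the true-loop class.
#' @param centroid Also report the ensemble centroid.
#' @param seed Integer seed recorded in the summary.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(guidance = NULL, candidates = NULL, shape = NULL,
                       patterns = NULL, model = NULL, out_dir = ".",
                       alpha = 0.05, top_k = 2L, fair_threshold = 1,
                       region_pad = 4L, posterior_cutoff = 0.5,
                       prior_true = 0.549, centroid = FALSE, seed = 1L,
                       log_level = "info") {
  structure(list(guidance = guidance, candidates = candidates, shape = shape,
                 patterns = patterns, model = model, out_dir = out_dir,
                 alpha = alpha, top_k = top_k,
                 fair_threshold = fair_threshold, region_pad = region_pad,
                 posterior_cutoff = posterior_cutoff, prior_true = prior_true,
                 centroid = centroid, seed = seed, log_level = log_level),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!purrr::map_lgl(unclass(config), is.null)],
                   path)
  invisible(path)
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[shaperefine] ", ...)
}

read_structure_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- trimws(lines[nzchar(trimws(lines))][1])
  if (startsWith(first, ">")) {
    read_structures(path)
  } else {
    list(structure_1 = parse_ct(lines))
  }
}

#' Run the refinement pipeline end to end
#'
#' Loads the guidance structure, candidate ensemble, SHAPE profile, pattern
#' table and posterior model named in the config; classifies the guidance
#' loops; selects the final structure; and writes the chosen structure
#' (dot-bracket and CT), a per-candidate audit TSV, a per-loop assessment
#' TSV and a JSON summary into `out_dir`. Partial outputs are removed on
#' failure.
#'
#' @param config A [run_config()] with all input paths set.
#' @return Invisibly, the `refinement_result`.
#' @export
run_pipeline <- function(config) {
  for (f in c("guidance", "candidates", "shape", "patterns", "model")) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  guidance <- read_structure_file(config$guidance)[[1]]
  candidates <- read_structures(config$candidates)
  profile <- read_shape(config$shape, length = rna_length(guidance))
  patterns <- read_patterns(config$patterns)
  model <- read_model(config$model)
  pipeline_log(config, "loaded ", length(candidates), " candidates, ",
               nrow(patterns), " patterns (seed ", config$seed,
               ", input checksum ",
               substr(paste(
                 tools::md5sum(c(config$guidance, config$candidates,
                                 config$shape, config$patterns,
                                 config$model)), collapse = ""), 1, 8),
               ")")

  result <- select_structure(guidance, candidates, profile, patterns, model,
                             fair_threshold = config$fair_threshold,
                             region_pad = config$region_pad,
                             posterior_cutoff = config$posterior_cutoff)
  chosen <- if (config$centroid) centroid_structure(candidates) else
    result$chosen

  p_db <- file.path(config$out_dir, "chosen.db")
  p_ct <- file.path(config$out_dir, "chosen.ct")
  p_audit <- file.path(config$out_dir, "audit.tsv")
  p_loops <- file.path(config$out_dir, "guidance_loops.tsv")
  p_sum <- file.path(config$out_dir, "summary.json")
  written <- c(p_db, p_ct, p_audit, p_loops, p_sum)

  write_structures(list(chosen = chosen), p_db)
  writeLines(write_ct(chosen, "chosen"), p_ct)
  utils::write.table(
    dplyr::select(result$audit, -"loops"), p_audit,
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    dplyr::mutate(
      dplyr::select(result$assessments, "loop_id", "loop_type", "motif",
                    "n_unpaired", "patterns_available", "penalty",
                    "category"),
      positions = purrr::map_chr(result$assessments$positions, paste,
                                 collapse = ",")),
    p_loops, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(chosen_index = result$chosen_index,
         fallback_used = result$fallback_used,
         total_penalty = result$total_penalty,
         centroid_requested = config$centroid,
         seed = config$seed,
         n_candidates = nrow(result$audit)),
    p_sum, auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  pipeline_log(config, "chose candidate ", result$chosen_index,
               " (total penalty ", signif(result$total_penalty, 4), ")")
  invisible(result)
}

#' Adapter for an external folding engine
#'
#' Runs a user-supplied folding command on a sequence (and optional SHAPE
#' file) and parses its dot-bracket output. The command template may use
#' the placeholders `{seq_file}` (a FASTA-like file holding the sequence)
#' and `{shape_file}`. The engine itself is never bundled: when the command
#' is not installed an informative error points to file-based input.
#'
#' @param sequence RNA sequence string.
#' @param command Command template whose first token is the engine binary.
#' @param profile Optional `shape_profile` written to `{shape_file}`.
#' @return A named list of [rna_structure] objects parsed from the
#'   engine's standard output (multi-record dot-bracket).
#' @export
external_fold <- function(sequence, command, profile = NULL) {
  binary <- strsplit(trimws(command), "\\s+")[[1]][1]
  if (Sys.which(binary) == "" && !file.exists(binary)) {
    stop("folding engine '", binary, "' is not installed; ",
         "supply guidance/candidate structures as files instead")
  }
  seq_file <- tempfile(fileext = ".fa")
  on.exit(unlink(seq_file), add = TRUE)
  writeLines(c(">query", sequence), seq_file)
  cmd <- sub("{seq_file}", seq_file, command, fixed = TRUE)
  if (grepl("{shape_file}", cmd, fixed = TRUE)) {
    shape_file <- tempfile(fileext = ".shape")
    on.exit(unlink(shape_file), add = TRUE)
    if (!is.null(profile)) write_shape(profile, shape_file)
    cmd <- sub("{shape_file}", shape_file, cmd, fixed = TRUE)
  }
  out <- system(cmd, intern = TRUE)
  tmp <- tempfile(fileext = ".db")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(out, tmp)
  read_structures(tmp)
}
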