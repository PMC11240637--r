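## End-to-end pipeline: haplotyping -> diversity statistics ->
## differentiation, with TSV/JSON reports and a run log.

#' Read a pipeline configuration file
#'
#' The configuration is a YAML key-value file with required keys `fasta`,
#' `metadata`, `reference`, `registry`, `out_dir`, and optional `window`
#' (`"start:end"`, default `"15386:16330"`), `L` (default 450), `n_perm`
#' (default 10000), `seed` (default 1), `allow_new` (default false) and
#' `digits` (display rounding, default 3).
#'
#' @param path YAML file path.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config Named list of configuration values.
#' @export
pipeline_config <- function(config) {
  required <- c("fasta", "metadata", "reference", "registry", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop(sprintf("config is missing key(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  defaults <- list(window = "15386:16330", L = 450L, n_perm = 10000L,
                   seed = 1L, allow_new = FALSE, digits = 3L)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("fasta", "metadata", "reference", "registry")) {
    if (!file.exists(config[[k]]))
      stop(sprintf("config error: '%s' file '%s' does not exist", k, config[[k]]),
           call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

parse_window_spec <- function(spec) {
  if (is.numeric(spec)) return(as.integer(spec[1:2]))
  parts <- as.integer(strsplit(as.character(spec), ":", fixed = TRUE)[[1]])
  if (length(parts) != 2 || any(is.na(parts)) || parts[2] <= parts[1])
    stop(sprintf("invalid window spec '%s' (expected start:end)", spec),
         call. = FALSE)
  parts
}

#' Run the full analysis pipeline
#'
#' Executes haplotyping, diversity statistics and pairwise differentiation
#' on a sample FASTA + metadata against a reference and haplotype registry,
#' writing TSV and JSON reports, the (possibly grown) registry, and a run
#' log recording the package version, seed and input digests. All numeric
#' report values are written at full precision with display-rounded
#' companions; rounding never feeds downstream computation.
#'
#' @param config A `pipeline_config`, a path to a YAML config file, or a
#'   named list of config values.
#' @return Invisibly, a list with `assignments`, `registry`, `stats`,
#'   `differentiation` and `paths` (the files written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- stage("load", {
    list(
      sequences = read_fasta(config$fasta),
      metadata = read_metadata(config$metadata),
      reference = read_reference(config$reference),
      registry = read_registry(config$registry)
    )
  })
  window <- parse_window_spec(config$window)

  hap <- stage("haplotype", {
    positioned <- map_sequences(inputs$sequences, inputs$reference, window)
    res <- assign_haplotypes(positioned, inputs$registry, inputs$reference,
                             allow_new = isTRUE(config$allow_new))
    c(res, list(positioned = positioned))
  })

  stats <- stage("stats", {
    stats_table(hap$positioned, hap$assignments, inputs$metadata,
                hap$registry, L = as.integer(config$L))
  })

  diffmat <- stage("differentiation", {
    tab <- haplotype_frequencies(hap$assignments, inputs$metadata)
    differentiation_matrix(tab, registry_diff_matrix(hap$registry),
                           n_perm = as.integer(config$n_perm),
                           seed = as.integer(config$seed))
  })

  paths <- stage("report", {
    write_reports(config, inputs, hap, stats, diffmat)
  })

  invisible(list(
    assignments = hap$assignments,
    registry = hap$registry,
    stats = stats,
    differentiation = diffmat,
    paths = paths
  ))
}

write_reports <- function(config, inputs, hap, stats, diffmat) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  digits <- as.integer(config$digits)
  paths <- c(
    assignments = file.path(out, "assignments.tsv"),
    stats_tsv = file.path(out, "stats.tsv"),
    stats_json = file.path(out, "stats.json"),
    diff_tsv = file.path(out, "differentiation.tsv"),
    diff_json = file.path(out, "differentiation.json"),
    registry = file.path(out, "registry.json"),
    log = file.path(out, "run_log.txt")
  )

  asn <- hap$assignments
  asn$haplotype_or_set <- ifelse(is.na(asn$haplotype),
                                 asn$consistent_with, asn$haplotype)
  utils::write.table(
    asn[, c("sample_id", "haplotype_or_set", "covered_start",
            "covered_end", "missing_sites")],
    paths[["assignments"]], sep = "\t", quote = FALSE, row.names = FALSE
  )

  ## stats TSV: regions as columns, statistics as rows (display-rounded;
  ## pi gets two extra decimals, matching survey-report convention)
  disp <- t(vapply(seq_len(nrow(stats)), function(i) {
    c(
      n = format(stats$n[i]),
      S = format(stats$S[i]),
      k = format(stats$k[i]),
      Hd = format(round_half_up(stats$Hd[i], digits), nsmall = digits),
      pi = format(round_half_up(stats$pi[i], digits + 2L), nsmall = digits + 2L),
      RMP = format(round_half_up(stats$RMP[i], digits), nsmall = digits)
    )
  }, character(6)))
  disp_t <- t(disp)
  colnames(disp_t) <- stats$region
  utils::write.table(
    cbind(statistic = rownames(disp_t), disp_t),
    paths[["stats_tsv"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(
      full_precision = stats,
      display = cbind(region = stats$region, as.data.frame(disp)),
      rmp_overall_pooled = attr(stats, "rmp_overall_pooled"),
      L = attr(stats, "L"),
      seed = as.integer(config$seed)
    ),
    paths[["stats_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  ## combined triangle TSV: Fst below the diagonal, Gst above
  comb <- diffmat$gst
  comb[lower.tri(comb)] <- diffmat$fst[lower.tri(diffmat$fst)]
  comb_disp <- matrix(
    ifelse(is.na(comb), "", format(round_half_up(comb, digits), nsmall = digits)),
    nrow(comb), dimnames = dimnames(comb)
  )
  utils::write.table(
    cbind(region = rownames(comb_disp), comb_disp),
    paths[["diff_tsv"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(
      regions = diffmat$regions,
      fst = diffmat$fst,
      gst = diffmat$gst,
      p_fst = diffmat$p_fst,
      p_gst = diffmat$p_gst,
      fst_threshold = diffmat$fst_threshold,
      significant_pairs = significant_pairs(diffmat),
      n_permutations = diffmat$n_permutations,
      seed = diffmat$seed
    ),
    paths[["diff_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  write_registry(hap$registry, paths[["registry"]])

  input_files <- unlist(config[c("fasta", "metadata", "reference", "registry")])
  log_lines <- c(
    sprintf("crhaplo %s", as.character(utils::packageVersion("crhaplo"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("window: %s  L: %d  n_perm: %d", config$window,
            as.integer(config$L), as.integer(config$n_perm)),
    sprintf("input %s: %s  md5=%s", names(input_files), input_files,
            tools::md5sum(input_files)),
    sprintf("samples: %d  regions: %d  haplotypes: %d",
            nrow(hap$assignments), length(diffmat$regions),
            length(hap$registry$haplotypes))
  )
  writeLines(log_lines, paths[["log"]])
  paths
}

significant_pairs <- function(diffmat) {
  sig <- which(diffmat$significant & upper.tri(diffmat$significant),
               arr.ind = TRUE)
  if (nrow(sig) == 0) return(list())
  lapply(seq_len(nrow(sig)), function(r) {
    i <- sig[r, 1]; j <- sig[r, 2]
    list(
      pair = paste(diffmat$regions[i], diffmat$regions[j], sep = "-"),
      fst = diffmat$fst[i, j]
    )
  })
}
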