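.RUN_DEFAULTS <- list(
  circular = NA, window = 50L, step = 50L, motif = "EACS",
  assoc_distance = 250L, report_window = 256L,
  weights = c(acs = 0.4, due = 0.3, at = 0.2, bend = 0.1),
  due = list(min_len = 30L, max_len = 100L, min_at = 0.60),
  curvature = list(params = "atract", half_window = 7L,
                   quantile = 0.95, reference = 1 / 42.8),
  seed = NULL)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration (same key structure as the defaults of
#' [runPipeline()]) and merges it over the defaults. Unknown keys are
#' an error so that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file, or a named list.
#' @return Named list of run parameters.
#' @export
loadRunConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  checkKeys <- function(given, allowed, where) {
    unknown <- setdiff(names(given), names(allowed))
    if (length(unknown))
      .stopf("unknown config key%s in %s: %s",
             if (length(unknown) > 1) "s" else "", where,
             paste(unknown, collapse = ", "))
  }
  checkKeys(cfg, .RUN_DEFAULTS, "run config")
  for (k in c("due", "curvature"))
    if (!is.null(cfg[[k]])) checkKeys(cfg[[k]], .RUN_DEFAULTS[[k]], k)
  out <- utils::modifyList(.RUN_DEFAULTS, cfg)
  if (!is.null(cfg$weights)) out$weights <- unlist(cfg$weights)
  out
}

#' Run the full origin-inference pipeline
#'
#' Wires the stages end-to-end for each input sequence: windowed
#' composition track, consensus motif scan, DUE detection, curvature
#' and bend analysis of every candidate window, origin calling, and a
#' machine-readable run manifest. All outputs are deterministic given
#' the configuration (and seed, when the input is generated).
#'
#' Outputs per sequence \code{<id>} under \code{outdir}:
#' \code{<id>.track.csv}, \code{<id>.motifs.bed},
#' \code{<id>.dues.bed}, \code{<id>.candidates.json}, and per
#' candidate \code{<id>.cand<k>.report.json} / \code{.report.txt} /
#' \code{.curvature.csv} / \code{.pdb}; plus \code{manifest.json}.
#'
#' @param input Path to a FASTA file, a [CircularSequence-class], or
#'   a list of them.
#' @param outdir Output directory (created if needed).
#' @param config Named list or YAML path accepted by
#'   [loadRunConfig()].
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(input, outdir, config = list()) {
  cfg <- loadRunConfig(config)
  if (is.character(input) && !file.exists(input))
    .stopf("input file not found: %s", input)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  checksum <- NA_character_
  if (is.character(input)) {
    checksum <- unname(tools::md5sum(input))
    seqs <- readFasta(input, circular = isTRUE(cfg$circular))
    if (!is.na(cfg$circular))
      seqs <- lapply(seqs, function(s)
        circularSequence(seqId(s), residues(s), cfg$circular))
  } else if (is(input, "CircularSequence")) {
    seqs <- list(input)
  } else seqs <- input
  ccfg <- callerConfig(assoc_distance = cfg$assoc_distance,
                       report_window = cfg$report_window,
                       weights = cfg$weights, due = cfg$due,
                       curvature = cfg$curvature)
  params <- loadWedgeParams(cfg$curvature$params)
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, basename(path)); path }
  for (s in seqs) {
    id <- seqId(s)
    track <- windowContent(s, window = cfg$window, step = cfg$step)
    exportTrack(track, emit(file.path(outdir,
                                      paste0(id, ".track.csv"))))
    hits <- scanMotif(s, cfg$motif, strands = "both")
    matchesToBed(hits, emit(file.path(outdir, paste0(id, ".motifs.bed"))),
                 seq_length = length(s))
    dues <- findATRichSegments(s, min_len = cfg$due$min_len,
                               max_len = cfg$due$max_len,
                               min_at = cfg$due$min_at)
    writeBed(data.frame(seq_id = id, start = dues$start,
                        end = dues$end,
                        label = sprintf("DUE%d", seq_len(nrow(dues))),
                        score = round(dues$at_fraction, 4),
                        strand = "."),
             emit(file.path(outdir, paste0(id, ".dues.bed"))),
             seq_length = length(s))
    cands <- callOrigins(s, config = ccfg, motif = cfg$motif,
                         dues = dues)
    jsonlite::write_json(
      candidateTable(cands),
      emit(file.path(outdir, paste0(id, ".candidates.json"))),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    for (k in seq_along(cands)) {
      cand <- cands[[k]]
      rep <- regionReport(cand, s)
      base <- file.path(outdir, sprintf("%s.cand%d", id, k))
      writeReport(rep, emit(paste0(base, ".report.json")),
                  emit(paste0(base, ".report.txt")))
      dna <- rep$sequence
      if (!grepl("N", dna, fixed = TRUE)) {
        p3d <- helicalPath(dna, params)
        prof <- curvatureProfile(p3d,
                                 half_window = cfg$curvature$half_window,
                                 circular = FALSE,
                                 reference = cfg$curvature$reference)
        utils::write.csv(
          data.frame(position = .wrap1(
                       cand@window[1] + seq_len(length(p3d)) - 1L,
                       length(s)),
                     curvature = prof@values,
                     normalized = prof@normalized),
          emit(paste0(base, ".curvature.csv")), row.names = FALSE)
        writePDB(p3d, emit(paste0(base, ".pdb")))
      }
    }
  }
  manifest <- list(
    package = "oriScan",
    version = as.character(utils::packageVersion("oriScan")),
    input = if (is.character(input)) input else "in-memory",
    input_md5 = checksum,
    sequences = vapply(seqs, seqId, character(1)),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    outputs = sort(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}
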