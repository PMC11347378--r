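#' Load and validate a run configuration
#'
#' Run configurations are YAML files (or lists) controlling the staged
#' pipeline commands. Recognized top-level keys: `mode`
#' (`"invitro"`/`"invivo"`), `library` (TSV path, or
#' `"example_invitro"`/`"example_invivo"`), `out_dir`, `seed`,
#' `replicates`, `n_mice`, `design` (arguments to [screen_design()]),
#' `fitness` (`editing` plus an `effects` list of
#' `{gene, lineage, fitness}` records), `sequencing` (`depth`,
#' `pcr_rho`), and `scoring` (`pseudocount`, `threshold`, `aggregation`,
#' `require_all_replicates`). Unknown keys are rejected so typos cannot
#' silently fall back to defaults. The full configuration is serialized
#' into the provenance header of every output file.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("mode", "library", "out_dir", "seed", "replicates",
             "n_mice", "design", "fitness", "sequencing", "scoring")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    abort(paste0("unknown config key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "dualscreen_config_error")
  defaults <- list(
    mode = "invitro", library = "example_invitro", out_dir = ".",
    seed = 1L, replicates = 2L, n_mice = 3L,
    design = list(), fitness = list(editing = 0.9, effects = list()),
    sequencing = list(depth = 1e6, pcr_rho = 0.001),
    scoring = list(pseudocount = 0.5, threshold = -1,
                   aggregation = "mean", require_all_replicates = TRUE)
  )
  cfg <- modifyList(defaults, config)
  if (!cfg$mode %in% c("invitro", "invivo"))
    abort("mode must be 'invitro' or 'invivo'",
          class = "dualscreen_config_error")
  structure(cfg, class = "run_config")
}

config_library <- function(cfg) {
  switch(cfg$library,
         example_invitro = example_invitro_library(),
         example_invivo = example_invivo_library(),
         read_library_tsv(cfg$library))
}

config_design <- function(cfg) {
  maker <- if (cfg$mode == "invitro") screen_design_invitro
           else screen_design_invivo
  do.call(maker, cfg$design)
}

config_fitness <- function(cfg) {
  eff <- if (length(cfg$fitness$effects))
    map_dfr(cfg$fitness$effects, as_tibble) else NULL
  fitness_model(effects = eff, editing = cfg$fitness$editing %||% 0.9)
}

# stable config hash for provenance: djb2 over the canonical deparse
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  m <- 2147483629
  h <- 5381
  for (c in utf8ToInt(txt)) h <- (h * 33 + c) %% m
  sprintf("%08x", h)
}

provenance_header <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL # where outputs land does not alter what they contain
  c(paste0("dualscreen ",
           as.character(utils::packageVersion("dualscreen"))),
    paste0("config_hash: ", config_hash(cfg)),
    paste0("seed: ", cfg$seed),
    paste0("config: ", jsonlite::toJSON(cfg, auto_unbox = TRUE)))
}

write_tsv_prov <- function(tb, path, cfg) {
  body <- strsplit(readr::format_tsv(as_tibble(tb)), "\n",
                   fixed = TRUE)[[1]]
  writeLines(c(paste0("# ", provenance_header(cfg)), body), path)
  invisible(path)
}

#' Staged pipeline commands
#'
#' Thin orchestration over the package's modules, mirroring how a screen
#' is actually processed: `run_simulate()` generates a synthetic screen
#' (flow tables for the culture arm; sorted counts, input frequencies and
#' a planted-truth fixture for the transplantation arm),
#' `run_count()` quantifies sgRNA barcodes from FASTQ into a count
#' matrix, `run_score()` turns flow or count tables into score, hit and
#' QC files, and `run_overlap()` tests two gene lists for overlap. All
#' outputs are TSV/JSON with provenance headers (package version, config
#' hash, seed), and identical inputs reproduce outputs byte for byte. The
#' same stages are exposed as subcommands of the bundled command-line
#' script (`system.file("cli", "dualscreen.R", package = "dualscreen")`).
#'
#' @param config A [run_config()] (or path / list coercible to one).
#' @return Invisibly, a named list of the files written.
#' @export
run_simulate <- function(config) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- config_library(cfg)
  design <- config_design(cfg)
  fitness <- config_fitness(cfg)
  out <- list()
  p <- function(f) file.path(cfg$out_dir, f)

  write_library_tsv(lib, p("library.tsv"))
  out$library <- p("library.tsv")
  write_truth_tsv(fitness, lib, p("truth.tsv"),
                  contexts = if (cfg$mode == "invivo")
                    design$lineages$lineage else "*")
  out$truth <- p("truth.tsv")

  if (cfg$mode == "invitro") {
    flow <- simulate_invitro_screen(lib, design, fitness,
                                    replicates = cfg$replicates,
                                    seed = cfg$seed)
    write_tsv_prov(flow, p("flow_counts.tsv"), cfg)
    out$flow <- p("flow_counts.tsv")
  } else {
    scr <- simulate_invivo_screen(lib, design, fitness,
                                  n_mice = cfg$n_mice, seed = cfg$seed)
    cm <- simulate_sequencing(scr$sorted, lib,
                              depth = cfg$sequencing$depth,
                              pcr_rho = cfg$sequencing$pcr_rho,
                              seed = cfg$seed)
    write_tsv_prov(scr$input_frequencies, p("input_frequencies.tsv"), cfg)
    write_tsv_prov(scr$lineage_state, p("lineage_state.tsv"), cfg)
    write_tsv_prov(cm, p("counts.tsv"), cfg)
    out$input_frequencies <- p("input_frequencies.tsv")
    out$lineage_state <- p("lineage_state.tsv")
    out$counts <- p("counts.tsv")
  }
  invisible(out)
}

#' @rdname run_simulate
#' @param sample_sheet Path to a TSV sample sheet (columns `file`,
#'   `sample_id`, plus metadata).
#' @param library Path to the library TSV.
#' @param layout A [read_layout()].
#' @param out_dir Output directory.
#' @export
run_count <- function(sample_sheet, library, layout = read_layout(),
                      out_dir = ".") {
  cfg <- run_config(list(library = library, out_dir = out_dir))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- readr::read_tsv(sample_sheet, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  lib <- read_library_tsv(library)
  res <- count_fastq(sheet, lib, layout)
  write_tsv_prov(res$counts, file.path(out_dir, "counts.tsv"), cfg)
  write_tsv_prov(res$stats, file.path(out_dir, "mapping_stats.tsv"), cfg)
  invisible(list(counts = file.path(out_dir, "counts.tsv"),
                 stats = file.path(out_dir, "mapping_stats.tsv")))
}

#' @rdname run_simulate
#' @param counts Path to a count matrix TSV (sequencing readout), or
#'   `NULL`.
#' @param flow Path to a flow-counts TSV (culture readout), or `NULL`.
#' @export
run_score <- function(config, counts = NULL, flow = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config)
                    else config)
  if (is.null(counts) == is.null(flow))
    abort("supply exactly one of counts= or flow=",
          class = "dualscreen_config_error")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$scoring
  p <- function(f) file.path(cfg$out_dir, f)

  if (!is.null(flow)) {
    fc <- readr::read_tsv(flow, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    st <- surpro_score(fc, pseudocount = sc$pseudocount)
    qc <- qc_screen(flow = fc, design = config_design(cfg))
  } else {
    cm <- read_count_tsv(counts)
    st <- abundance_score(normalize_cpm(cm,
                                        pseudocount = sc$pseudocount))
    qc <- qc_screen(cm = cm, design = config_design(cfg))
  }
  gs <- gene_score(st, method = sc$aggregation)
  hits <- call_hits(gs, threshold = sc$threshold,
                    require_all_replicates = sc$require_all_replicates)
  write_tsv_prov(st, p("guide_scores.tsv"), cfg)
  write_tsv_prov(gs, p("gene_scores.tsv"), cfg)
  write_tsv_prov(hits, p("hits.tsv"), cfg)
  jsonlite::write_json(
    list(provenance = provenance_header(cfg),
         sections = lapply(unclass(qc), as.data.frame),
         ok = attr(qc, "ok")),
    p("qc.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(guide_scores = p("guide_scores.tsv"),
                 gene_scores = p("gene_scores.tsv"),
                 hits = p("hits.tsv"), qc = p("qc.json")))
}

#' @rdname run_simulate
#' @param set_a,set_b Paths to gene-list files (one symbol per line, or
#'   scored TSV from which the top decile is taken).
#' @param universe_size Universe size for [overlap_test()].
#' @param q Percentile used when a scored TSV is supplied.
#' @param out Output JSON path.
#' @export
run_overlap <- function(set_a, set_b, universe_size, q = 0.90,
                        out = "overlap.json") {
  load_set <- function(path, nm) {
    first <- readLines(path, n = 1)
    if (grepl("\tscore|^gene\t", first))
      percentile_target_set(read_gene_scores(path), q = q, name = nm)
    else gene_set(read_gene_list(path), name = nm)
  }
  a <- load_set(set_a, "A")
  b <- load_set(set_b, "B")
  res <- overlap_test(a, b, universe_size)
  jsonlite::write_json(glance(res), out, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(res)
}
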