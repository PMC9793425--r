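## Readers/writers for the tab-separated segment-table formats produced by
## IBD/ROH callers, binned-count TSVs with JSON metadata sidecars, YAML
## model/config serialization, and the pipeline driver.

## required columns per dialect; units are declared in the header and never
## silently coerced
.DIALECT_COLS <- list(
  ibd = c("sample1", "sample2", "chromosome", "length_cM"),
  roh = c("sample", "chromosome", "start_cM", "end_cM", "length_cM"))

#' Read a tab-separated segment table
#'
#' Reads IBDseq-style pairwise IBD tables (\code{dialect = "ibd"}: columns
#' \code{sample1}, \code{sample2}, \code{chromosome}, \code{length_cM}) or
#' hapROH-style per-individual ROH tables (\code{dialect = "roh"}: columns
#' \code{sample}, \code{chromosome}, \code{start_cM}, \code{end_cM},
#' \code{length_cM}).  Genetic-length units must be declared in the header
#' via the \code{_cM} suffix: a \code{length} column with no unit, or one
#' declared in Morgans, is an error, never an auto-detected conversion.
#' Malformed rows (non-numeric, non-positive or inconsistent lengths) are
#' rejected with their line numbers.
#'
#' @param path file path.
#' @param dialect \code{"ibd"} or \code{"roh"}.
#' @return Segment records (for \code{"ibd"}, \code{sample} is the
#'   concatenated pair id and \code{start_cM}/\code{end_cM} are carried
#'   through if present).  Rejected rows are reported via a warning and the
#'   \code{"rejected"} attribute (line numbers).
#' @export
readSegmentTable <- function(path, dialect = c("ibd", "roh")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- .DIALECT_COLS[[dialect]]
  unitless <- intersect(c("length", "start", "end", "length_M", "start_M",
                          "end_M"), names(tab))
  if (length(unitless))
    stop("genetic lengths must be declared in cM via the _cM column ",
         "suffix; found: ", paste(unitless, collapse = ", "))
  if (!all(need %in% names(tab)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))

  len <- suppressWarnings(as.numeric(tab$length_cM))
  bad <- !is.finite(len) | len <= 0
  if (dialect == "roh") {
    s <- suppressWarnings(as.numeric(tab$start_cM))
    e <- suppressWarnings(as.numeric(tab$end_cM))
    bad <- bad | !is.finite(s) | !is.finite(e) | e <= s |
      abs((e - s) - len) > 1e-6
  }
  if (any(bad))
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  tab <- tab[!bad, , drop = FALSE]
  out <- if (dialect == "roh") {
    data.frame(sample = as.character(tab$sample),
               chromosome = as.character(tab$chromosome),
               start_cM = as.numeric(tab$start_cM),
               end_cM = as.numeric(tab$end_cM),
               length_cM = as.numeric(tab$length_cM))
  } else {
    data.frame(sample = paste(tab$sample1, tab$sample2, sep = "|"),
               chromosome = as.character(tab$chromosome),
               start_cM = if ("start_cM" %in% names(tab))
                 as.numeric(tab$start_cM) else 0,
               end_cM = if ("end_cM" %in% names(tab))
                 as.numeric(tab$end_cM) else as.numeric(tab$length_cM),
               length_cM = as.numeric(tab$length_cM))
  }
  attr(out, "rejected") <- which(bad) + 1L
  out
}

#' Write / read a binned count table as TSV + JSON sidecar
#'
#' The TSV holds \code{bin_low}, \code{bin_high}, \code{count}; the JSON
#' sidecar (\code{<path>.json}) holds the cohort metadata (n, pair count,
#' sampling mode and time, consanguinity, label) needed to reconstruct the
#' [SegmentCountTable-class].
#'
#' @param table a [SegmentCountTable-class].
#' @param path TSV output path.
#' @return \code{writeCountTable}: \code{path}, invisibly;
#'   \code{readCountTable}: the reconstructed table.
#' @export
writeCountTable <- function(table, path) {
  stopifnot(is(table, "SegmentCountTable"))
  e <- binEdges(table)
  utils::write.table(
    data.frame(bin_low = e[-length(e)], bin_high = e[-1],
               count = binCounts(table)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- table@sampling
  meta <- list(n_individuals = table@nIndividuals, n_pairs = table@nPairs,
               mode = s@mode, sample_time = s@sampleTime,
               no_recent_coalescence = s@noRecentCoalescence,
               kappa = s@kappa, pedigree_loop_time = s@pedigreeLoopTime,
               pedigree_loop_prob = s@pedigreeLoopProb,
               subpop = if (is.na(s@subpop)) NULL else s@subpop,
               label = table@label)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
  tab <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bins <- LengthBins(edgesCM = c(tab$bin_low, tab$bin_high[nrow(tab)]))
  sampling <- SamplingSpec(
    sampleTime = meta$sample_time, mode = meta$mode,
    noRecentCoalescence = meta$no_recent_coalescence,
    kappa = meta$kappa %||% 0,
    pedigreeLoopTime = meta$pedigree_loop_time %||% 3,
    pedigreeLoopProb = meta$pedigree_loop_prob %||% (1 / 16),
    subpop = meta$subpop %||% NA_character_)
  SegmentCountTable(counts = tab$count, bins = bins,
                    nIndividuals = meta$n_individuals %||% NA_real_,
                    nPairs = meta$n_pairs, sampling = sampling,
                    label = meta$label %||% "")
}

## ---- YAML model serialization ---------------------------------------------

#' Serialize demographic models and sampling specs to and from YAML
#'
#' Models are written as flat YAML blocks
#' (\code{model: single|two_pop, N_a:, N_b:, T_b:, d:, N_c:[, f:, N_g:]}),
#' sampling specs analogously.
#'
#' @param model a [DemographicModel-class].
#' @param x a YAML string, a parsed list, or a file path.
#' @param file optional path to write to.
#' @return \code{modelToYAML}: the YAML string (invisibly when writing to a
#'   file); \code{modelFromYAML}: the model object.
#' @examples
#' modelFromYAML(modelToYAML(SinglePopModel(Na = 1e4, Nb = 1563, Tb = 41,
#'                                          d = 20, Nc = 1e6)))
#' @export
modelToYAML <- function(model, file = NULL) {
  stopifnot(is(model, "DemographicModel"))
  lst <- list(model = if (is(model, "TwoPopModel")) "two_pop" else "single",
              N_a = model@Na, N_b = model@Nb, T_b = model@Tb, d = model@d,
              N_c = model@Nc)
  if (is(model, "TwoPopModel")) {
    lst$f <- model@f
    lst$N_g <- model@Ng
  }
  txt <- yaml::as.yaml(lst)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname modelToYAML
#' @export
modelFromYAML <- function(x) {
  lst <- if (is.list(x)) x
         else if (length(x) == 1 && file.exists(x)) yaml::read_yaml(x)
         else yaml::yaml.load(x)
  type <- lst$model %||% "single"
  if (type == "two_pop")
    TwoPopModel(Na = lst$N_a, Nb = lst$N_b, Tb = lst$T_b, d = lst$d,
                Nc = lst$N_c, f = lst$f, Ng = lst$N_g %||% lst$N_b)
  else
    SinglePopModel(Na = lst$N_a, Nb = lst$N_b, Tb = lst$T_b, d = lst$d,
                   Nc = lst$N_c)
}

## ---- run configuration and pipeline ---------------------------------------

#' Load and validate a YAML run configuration
#'
#' The configuration drives [runPipeline()]: input count-table paths (or a
#' \code{simulate} block), replicate counts, seeds and the output
#' directory.  Referenced paths must exist at load time; seeds must be
#' integers.
#'
#' @param path YAML file path.
#' @return The validated configuration list (class
#'   \code{"ibdemogRunConfig"}), with the canonical-config MD5 hash in
#'   attribute \code{"configHash"}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("ibd_counts", "roh_counts")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured path does not exist: ", cfg[[key]], " (", key, ")")
  }
  cfg$seed <- cfg$seed %||% 1L
  if (cfg$seed != round(cfg$seed)) stop("seeds must be integers")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_bootstrap <- as.integer(cfg$n_bootstrap %||% 100L)
  cfg$n_selection <- as.integer(cfg$n_selection %||% 100L)
  cfg$out_dir <- cfg$out_dir %||% "ibdemog_out"
  attr(cfg, "configHash") <- .configHash(cfg)
  class(cfg) <- "ibdemogRunConfig"
  cfg
}

## MD5 of the canonicalized (sorted, JSON-serialized) configuration; the
## output location is not part of the analysis-defining inputs
.configHash <- function(cfg) {
  attributes(cfg) <- attributes(cfg)["names"]
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full inference pipeline
#'
#' Stage sequence: acquire data (read binned count tables, or generate a
#' synthetic study when the configuration has a \code{simulate} block) →
#' fit the single-population model → fit the two-population model →
#' parametric-bootstrap confidence intervals → bootstrap model selection.
#' Deterministic given the configured seeds; every intermediate table and a
#' structured log are persisted under \code{out_dir}, every JSON output
#' embeds the seed and the configuration hash, and a stage failure aborts
#' with the stage name after writing partial outputs.
#'
#' Stages can be restricted via \code{config$stages} (default all); with
#' ROH-only data the IBD-specific stages are skipped.
#'
#' @param config an \code{"ibdemogRunConfig"} (see [readRunConfig()]) or an
#'   equivalent list.
#' @param genome a [GenomeMap-class].
#' @return A list with the fits, intervals and selection results.
#' @export
runPipeline <- function(config, genome = defaultGenomeMap()) {
  cfg <- config
  if (!inherits(cfg, "ibdemogRunConfig")) {
    cfg$seed <- as.integer(cfg$seed %||% 1L)
    cfg$n_bootstrap <- as.integer(cfg$n_bootstrap %||% 100L)
    cfg$n_selection <- as.integer(cfg$n_selection %||% 100L)
    cfg$out_dir <- cfg$out_dir %||% "ibdemog_out"
    attr(cfg, "configHash") <- .configHash(cfg)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$out_dir, "pipeline.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logPath, append = TRUE)
  }
  results <- list(configHash = attr(cfg, "configHash"), seed = cfg$seed)
  persist <- function(name, obj) {
    jsonlite::write_json(c(list(seed = cfg$seed,
                                config_hash = attr(cfg, "configHash")), obj),
                         file.path(cfg$out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  stage <- function(name, expr) {
    logLine("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      persist("failure", list(stage = name, error = conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stages <- cfg$stages %||% c("data", "fit_single", "fit_two_pop",
                              "bootstrap", "select")

  datasets <- stage("data", {
    if (!is.null(cfg$simulate)) {
      simCfg <- cfg$simulate
      if (!is.null(simCfg$model)) simCfg$model <- modelFromYAML(simCfg$model)
      study <- generateStudy(simCfg, seed = cfg$seed, genome = genome)
      writeCountTable(study@ibd, file.path(cfg$out_dir, "ibd_counts.tsv"))
      writeCountTable(study@roh, file.path(cfg$out_dir, "roh_counts.tsv"))
      list(ibd = study@ibd, roh = study@roh)
    } else {
      ds <- list()
      if (!is.null(cfg$ibd_counts)) ds$ibd <- readCountTable(cfg$ibd_counts)
      if (!is.null(cfg$roh_counts)) ds$roh <- readCountTable(cfg$roh_counts)
      if (length(ds) == 0) stop("no input data configured")
      ds
    }
  })
  logLine("data: ", paste(names(datasets), collapse = " + "))

  fitEntry <- function(fit) list(
    model_type = fit@modelType, estimates = as.list(fit@estimates),
    fixed = as.list(fit@space@fixed), loglik = fit@loglik,
    converged = fit@diagnostics$converged,
    iterations = fit@diagnostics$iterations,
    optimizer_seed = fit@diagnostics$seed,
    ci = if (nrow(fit@ci)) apply(fit@ci, 1, as.list, simplify = FALSE))

  ctl <- cfg$control %||% list()
  if ("fit_single" %in% stages) {
    results$single <- stage("fit_single",
      fitModel(unname(datasets), "single", genome = genome,
               seed = cfg$seed, control = ctl))
    persist("fit_single", fitEntry(results$single))
    logLine("single-population fit: loglik ", results$single@loglik)
  }
  if ("fit_two_pop" %in% stages) {
    results$twoPop <- stage("fit_two_pop", {
      ds2 <- lapply(unname(datasets), .assignSubpop,
                    cfg$roh_subpop %||% "bottleneck")
      ctl2 <- ctl
      if (!is.null(results$single))
        ctl2$init <- .twoPopInit(results$single@estimates,
                                 defaultParameterSpace("two_pop"))
      fitModel(ds2, "two_pop", genome = genome, seed = cfg$seed,
               control = ctl2)
    })
    persist("fit_two_pop", fitEntry(results$twoPop))
    logLine("two-population fit: loglik ", results$twoPop@loglik)
  }
  if ("bootstrap" %in% stages && !is.null(results$single)) {
    results$single <- stage("bootstrap",
      bootstrapCI(results$single, unname(datasets),
                  nReplicates = cfg$n_bootstrap, genome = genome,
                  seed = cfg$seed, control = ctl))
    persist("fit_single", fitEntry(results$single))
    logLine("bootstrap intervals over ", cfg$n_bootstrap, " replicates")
  }
  if ("select" %in% stages && !is.null(results$single) &&
      !is.null(results$twoPop)) {
    sel <- stage("select",
      modelSelectionBootstrap(unname(datasets),
                              nReplicates = cfg$n_selection,
                              genome = genome, seed = cfg$seed,
                              control = ctl,
                              rohSubpop = cfg$roh_subpop %||% "bottleneck"))
    results$selection <- sel
    persist("selection", list(p = sel$p, delta = sel$delta,
                              delta_null = sel$deltaNull))
    logLine("model selection: p = ", sel$p)
  }
  logLine("pipeline complete")
  results
}
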