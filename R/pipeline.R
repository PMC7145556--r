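.PIPELINE_STAGES <- c("simulate", "process", "metagene", "queue", "enrich",
                      "readthrough")
.STAGE_DEPS <- list(simulate = character(0), process = "simulate",
                    metagene = "process", queue = "process",
                    enrich = "queue", readthrough = "process")

#' Default pipeline configuration
#'
#' A two-temperature, two-genotype, two-replicate design mirroring a typical
#' wild-type versus termination-factor-deletion Ribo-Seq experiment: the
#' mutant libraries carry queue peaks (full amplitude at the
#' growth-restrictive low temperature, half at the permissive one), the
#' wild-type libraries none. All analysis thresholds are surfaced here.
#'
#' @param seed integer master seed; every library derives its own seed from
#'   it.
#' @param nOrfs number of ORFs in the shared annotation.
#' @return a nested configuration list accepted by \code{\link{runPipeline}};
#'   the same structure can be stored as / read from YAML.
#' @export
defaultPipelineConfig <- function(seed = 1L, nOrfs = 200L) {
  list(
    seed = as.integer(seed),
    stages = .PIPELINE_STAGES,
    sim = list(nOrfs = as.integer(nOrfs)),
    conditions = list(
      wt_20C = list(replicates = 2L, queueAmplitude = 0),
      new1d_20C = list(replicates = 2L),
      wt_30C = list(replicates = 2L, queueAmplitude = 0),
      new1d_30C = list(replicates = 2L, queueAmplitude = 25)
    ),
    pool_replicates = TRUE,
    offsets = NULL,
    metagene = list(window = c(-120L, 60L), minWindowMeanRpm = 0),
    queue = list(minCoverage = 10, zCutoff = 1, spacing = 30L, halfWidth = 5L),
    enrich = list(windowCodons = 7L, alpha = 0.05),
    readthrough = list(utrWindow = c(3L, 63L), orfWindow = c(-120L, 0L)),
    out_dir = NULL
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' \code{\link{defaultPipelineConfig}}; \code{conditions}, when given,
#' replaces the default design wholesale.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig(seed = user$seed %||% 1L)
  for (nm in names(user)) {
    if (nm %in% c("metagene", "queue", "enrich", "readthrough", "sim")) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

.validatePipelineConfig <- function(config) {
  stages <- config$stages
  bad <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!length(stages)) stop("no stages requested")
  if (is.null(config$seed)) stop("config must carry a seed")
  if (!is.null(config$conditions)) {
    if (is.null(names(config$conditions)) || any(names(config$conditions) == ""))
      stop("conditions must be a named list")
  }
  invisible(config)
}

.simConfigFor <- function(config, overrides = list(), drop = "replicates") {
  args <- config$sim %||% list()
  overrides <- overrides[setdiff(names(overrides), drop)]
  args[names(overrides)] <- overrides
  args$seed <- args$seed %||% config$seed
  do.call(simConfig, args)
}

#' Run the queuing-analysis pipeline
#'
#' Executes the requested stages in order -- simulate, process (P-site
#' assignment, RPM, pooling), metagene (+ wave period), queue (coverage
#' filter, Q, Z-selection, C-terminal grouping), enrich (positional
#' log-odds, stop-codon context and identity test) and readthrough -- from a
#' single configuration, logging per-stage read/drop accounting. The run is
#' deterministic for a fixed configuration (the master seed derives one seed
#' per simulated library). When later stages are requested without their
#' upstream stage, pass a previous result bundle.
#'
#' @param config configuration list (\code{\link{defaultPipelineConfig}},
#'   \code{\link{readPipelineConfig}}) or a path to a YAML file.
#' @param bundle optional bundle from a previous run providing the outputs
#'   of stages not being re-run.
#' @return a result bundle: list with (depending on stages) \code{dataset},
#'   \code{libraries}, \code{tracks} (per condition, pooled and
#'   RPM-normalised), \code{libStats}, \code{metagene} (profile + period per
#'   condition), \code{scores}, \code{selected}, \code{byCterm},
#'   \code{enrichment}, \code{stopContext}, \code{stopIdentity},
#'   \code{readthrough}, plus \code{config}, \code{configHash} and
#'   \code{log}. If \code{config$out_dir} is set the bundle is also written
#'   via \code{\link{writeReports}}.
#' @examples
#' cfg <- defaultPipelineConfig(seed = 7, nOrfs = 30)
#' cfg$stages <- c("simulate", "process")
#' cfg$conditions <- list(new1d = list(replicates = 1L))
#' b <- runPipeline(cfg)
#' names(b)
#' @export
runPipeline <- function(config, bundle = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  .validatePipelineConfig(config)
  stages <- config$stages
  for (st in stages) {
    dep <- .STAGE_DEPS[[st]]
    if (length(dep) && !dep %in% stages && is.null(bundle))
      stop("stage '", st, "' requires stage '", dep,
           "' (or a bundle providing its outputs)")
  }
  out <- bundle %||% list()
  out$config <- config
  # the hash identifies the analysis, not where its reports land
  out$configHash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  logLines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message("[riboQueue] ", line)
    logLines <<- c(logLines, line)
  }

  offsets <- if (is.null(config$offsets)) defaultOffsets() else loadOffsets(config$offsets)
  conditions <- config$conditions %||% list(sample = list(replicates = 1L))

  if ("simulate" %in% stages) {
    baseCfg <- .simConfigFor(config)
    out$dataset <- generateAnnotation(baseCfg)
    say("simulate: %d ORFs (seed %d)", nrow(out$dataset$annotation), baseCfg@seed)
    out$libraries <- list()
    libSeed <- config$seed
    for (cn in names(conditions)) {
      ccfg <- .simConfigFor(config, conditions[[cn]])
      nRep <- conditions[[cn]]$replicates %||% 1L
      for (r in seq_len(nRep)) {
        libSeed <- libSeed + 1L
        lib <- simulateFootprints(ccfg, out$dataset$annotation,
                                  out$dataset$truth, seed = libSeed,
                                  offsets = offsets)
        out$libraries[[paste0(cn, "_rep", r)]] <-
          c(lib, list(condition = cn))
        say("simulate: %s_rep%d: %d reads (%d dropped)", cn, r,
            lib$librarySize, lib$dropped)
      }
    }
  }

  if ("process" %in% stages) {
    if (is.null(out$libraries) || is.null(out$dataset))
      stop("stage 'process' requires stage 'simulate' outputs")
    txLen <- .txLengths(out$dataset$annotation)
    perLib <- lapply(names(out$libraries), function(nm) {
      lib <- out$libraries[[nm]]
      res <- assignPsites(lib$alignments, offsets, txLen,
                          condition = lib$condition)
      say("process: %s: %d assigned, %d dropped", nm,
          res$stats$assigned, res$stats$dropped)
      res
    })
    names(perLib) <- names(out$libraries)
    out$libStats <- lapply(perLib, `[[`, "stats")
    byCond <- split(perLib, vapply(out$libraries, `[[`, "", "condition"))
    pool <- isTRUE(config$pool_replicates %||% TRUE)
    out$tracks <- lapply(names(byCond), function(cn) {
      reps <- lapply(byCond[[cn]], `[[`, "tracks")
      if (pool) poolLibraries(reps, condition = cn)
      else normalizeRpm(reps[[1]])
    })
    names(out$tracks) <- names(byCond)
    # keep declared condition order
    out$tracks <- out$tracks[intersect(names(conditions), names(out$tracks))]
  }

  if ("metagene" %in% stages) {
    if (is.null(out$tracks)) stop("stage 'metagene' requires stage 'process'")
    mg <- config$metagene
    out$metagene <- lapply(out$tracks, function(tr) {
      prof <- metageneProfile(tr, out$dataset$annotation,
                              window = mg$window,
                              minWindowMeanRpm = mg$minWindowMeanRpm)
      per <- wavePeriod(prof)
      say("metagene: %s: %d genes, wave period %s", conditionLabel(tr),
          prof@nGenes,
          if (is.na(per)) "not detected" else paste(format(per), "nt"))
      list(profile = prof, period = per)
    })
  }

  if ("queue" %in% stages) {
    if (is.null(out$tracks)) stop("stage 'queue' requires stage 'process'")
    qc <- config$queue
    out$queueConfig <- queuingConfig(
      layout = peakLayout(spacing = qc$spacing %||% 30L,
                          halfWidth = qc$halfWidth %||% 5L),
      minCoverage = qc$minCoverage %||% 10,
      zCutoff = qc$zCutoff %||% 1)
    out$scores <- scoreAll(out$tracks, out$dataset$annotation, out$queueConfig)
    nPass <- sum(attr(out$scores, "filter")$pass)
    say("queue: %d ORFs pass the coverage filter; mean Q: %s", nPass,
        paste(sprintf("%s=%.2f", names(attr(out$scores, "meanQ")),
                      attr(out$scores, "meanQ")), collapse = ", "))
    out$selected <- lapply(split(out$scores, out$scores$condition),
                           zscoreSelect, cutoff = out$queueConfig$zCutoff)
    out$byCterm <- lapply(split(out$scores, out$scores$condition), groupByCterm)
  }

  if ("enrich" %in% stages) {
    if (is.null(out$scores)) stop("stage 'enrich' requires stage 'queue'")
    en <- config$enrich
    ann <- out$dataset$annotation
    seqs <- out$dataset$sequences
    filtered <- attr(out$scores, "filter")
    universe <- filtered$transcript_id[filtered$pass]
    bgWin <- ctermWindow(ann, seqs, universe, windowCodons = en$windowCodons)
    bg <- backgroundFrequencies(bgWin, source = "coverage-filtered ORFs")
    out$enrichment <- list()
    out$stopContext <- list()
    out$stopIdentity <- list()
    for (cn in names(out$selected)) {
      sel <- out$selected[[cn]]$orf_id
      if (!length(sel)) {
        say("enrich: %s: no selected ORFs", cn)
        next
      }
      fgWin <- ctermWindow(ann, seqs, sel, windowCodons = en$windowCodons)
      out$enrichment[[cn]] <- positionalLogodds(fgWin, bg, alpha = en$alpha)
      out$stopContext[[cn]] <- stopCodonContext(sel, ann, seqs,
                                                backgroundIds = universe,
                                                alpha = en$alpha)
      out$stopIdentity[[cn]] <- tryCatch(
        stopIdentityAssociation(out$scores[out$scores$condition == cn, ]),
        error = function(e) NULL)
      nSig <- sum(out$enrichment[[cn]]$significant)
      say("enrich: %s: %d selected ORFs, %d significant position/residue pairs",
          cn, length(sel), nSig)
    }
  }

  if ("readthrough" %in% stages) {
    if (is.null(out$tracks)) stop("stage 'readthrough' requires stage 'process'")
    rt <- config$readthrough
    out$readthrough <- lapply(out$tracks, function(tr)
      readthroughScores(tr, out$dataset$annotation,
                        utrWindow = rt$utrWindow, orfWindow = rt$orfWindow))
    say("readthrough: scored %d ORFs per condition",
        nrow(out$readthrough[[1]]))
  }

  out$log <- logLines
  if (!is.null(config$out_dir)) writeReports(out, config$out_dir)
  out
}

.reportHeader <- function(bundle) {
  sprintf("# riboQueue %s | config_hash=%s | seed=%s | offsets=%s",
          as.character(utils::packageVersion("riboQueue")),
          bundle$configHash, bundle$config$seed,
          if (length(bundle$tracks)) bundle$tracks[[1]]@offsetsProvenance
          else "unspecified")
}

.writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write pipeline reports
#'
#' Emits TSV tables (scores, C-terminal summary, enrichment, stop-codon
#' context, readthrough, metagene profiles, library statistics), one
#' bedGraph coverage track per condition, and a JSON manifest listing every
#' written file with its MD5 checksum together with the package version,
#' configuration hash and seed. Every TSV carries a provenance header line.
#'
#' @param bundle result bundle from \code{\link{runPipeline}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
writeReports <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- .reportHeader(bundle)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    .writeTsv(df, p, hdr)
    files <<- c(files, p)
  }
  if (!is.null(bundle$dataset)) {
    emit(bundle$dataset$annotation, "annotation.tsv")
    emit(bundle$dataset$truth, "truth.tsv")
  }
  if (!is.null(bundle$libStats)) {
    st <- do.call(rbind, lapply(names(bundle$libStats), function(nm) {
      s <- bundle$libStats[[nm]]
      data.frame(library = nm, total = s$total, assigned = s$assigned,
                 dropped = s$dropped, short_fraction = s$shortFraction,
                 long_fraction = s$longFraction, stringsAsFactors = FALSE)
    }))
    emit(st, "library_stats.tsv")
  }
  if (!is.null(bundle$tracks)) {
    for (cn in names(bundle$tracks)) {
      p <- file.path(dir, paste0("coverage_", cn, ".bedGraph"))
      .writeBedGraph(bundle$tracks[[cn]], p)
      files <- c(files, p)
    }
  }
  if (!is.null(bundle$metagene)) {
    mg <- do.call(rbind, lapply(names(bundle$metagene), function(cn) {
      prof <- bundle$metagene[[cn]]$profile
      data.frame(condition = cn, position = prof@position,
                 density = prof@density, n_genes = prof@nGenes,
                 stringsAsFactors = FALSE)
    }))
    emit(mg, "metagene.tsv")
  }
  if (!is.null(bundle$scores)) {
    emit(bundle$scores, "queuing_scores.tsv")
    ct <- do.call(rbind, lapply(names(bundle$byCterm), function(cn)
      cbind(condition = cn, bundle$byCterm[[cn]]$summary)))
    emit(ct, "queuing_by_cterm.tsv")
  }
  if (length(bundle$enrichment)) {
    enr <- do.call(rbind, lapply(names(bundle$enrichment), function(cn)
      cbind(condition = cn, bundle$enrichment[[cn]])))
    emit(enr, "enrichment.tsv")
    sc <- do.call(rbind, lapply(names(bundle$stopContext), function(cn)
      cbind(condition = cn, bundle$stopContext[[cn]])))
    emit(sc, "stop_context.tsv")
  }
  if (!is.null(bundle$readthrough)) {
    rt <- do.call(rbind, lapply(names(bundle$readthrough), function(cn)
      cbind(condition = cn, bundle$readthrough[[cn]])))
    emit(rt, "readthrough.tsv")
  }
  manifest <- list(
    package = "riboQueue",
    version = as.character(utils::packageVersion("riboQueue")),
    config_hash = bundle$configHash,
    seed = bundle$config$seed,
    files = lapply(files, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p)))))
  if (!length(files)) warning("empty bundle: manifest lists no artifacts")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.writeBedGraph <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"",
                     conditionLabel(tracks)), con)
  r <- rpm(tracks)
  for (tx in names(r)) {
    v <- r[[tx]]
    nz <- which(v > 0)
    if (!length(nz)) next
    runs <- split(nz, cumsum(c(1L, diff(nz) != 1L | diff(v[nz]) != 0)))
    for (run in runs) {
      writeLines(sprintf("%s\t%d\t%d\t%g", tx, run[1] - 1L,
                         run[length(run)], v[run[1]]), con)
    }
  }
}
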