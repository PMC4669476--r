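#' Write an EMG study to a plain-text directory layout
#'
#' One tab-separated numeric table per trial (columns = channels, header =
#' channel labels, rows = samples) plus a `study.yaml` sidecar holding the
#' sampling rate, channel labels, branch tag, trial annotations and
#' provenance. The layout is the native on-disk format both the generator
#' and [readEmgStudy()] use.
#'
#' @param study an [EmgStudy-class].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
writeEmgStudy <- function(study, path) {
  stopifnot(is(study, "EmgStudy"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  info <- study@info
  files <- sprintf("trial_%03d_%s_%s_%d.tsv", seq_len(nrow(info)),
                   info$subject, info$condition, info$trial)
  for (i in seq_along(files)) {
    m <- t(study@trials[[i]])
    colnames(m) <- study@channelLabels
    utils::write.table(m, file.path(path, files[i]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  meta <- list(fs = study@fs, channelLabels = as.list(study@channelLabels),
               branch = study@branch,
               trials = lapply(seq_len(nrow(info)), function(i)
                 list(file = files[i], subject = info$subject[i],
                      condition = info$condition[i], trial = info$trial[i])),
               provenance = serializableProvenance(study@provenance))
  yaml::write_yaml(meta, file.path(path, "study.yaml"))
  invisible(path)
}

# Provenance may hold S3 spec objects; flatten to plain lists for YAML.
serializableProvenance <- function(p) {
  rapply(p, function(x) {
    if (is.matrix(x)) apply(x, 1L, as.numeric, simplify = FALSE) else x
  }, how = "replace")
}

#' Read an EMG study from the on-disk layout
#'
#' Validates the `study.yaml` sidecar and every trial table; error messages
#' name the offending file and column.
#'
#' @param path study directory written by [writeEmgStudy()].
#' @return an [EmgStudy-class].
#' @export
readEmgStudy <- function(path) {
  sidecar <- file.path(path, "study.yaml")
  if (!file.exists(sidecar))
    stop("missing study sidecar: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  for (field in c("fs", "channelLabels", "trials"))
    if (is.null(meta[[field]]))
      stop("sidecar ", sidecar, " lacks required field '", field, "'")
  labels <- unlist(meta$channelLabels)
  trials <- vector("list", length(meta$trials))
  info <- data.frame(subject = character(), condition = character(),
                     trial = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(meta$trials)) {
    tr <- meta$trials[[i]]
    f <- file.path(path, tr$file)
    if (!file.exists(f)) stop("missing trial file: ", f)
    tab <- utils::read.table(f, header = TRUE, sep = "\t",
                             check.names = FALSE)
    missingCols <- setdiff(labels, names(tab))
    if (length(missingCols))
      stop("trial file ", tr$file, " is missing channel column(s): ",
           paste(missingCols, collapse = ", "))
    tab <- tab[, labels, drop = FALSE]
    if (!all(vapply(tab, is.numeric, TRUE)))
      stop("trial file ", tr$file, " contains non-numeric cells")
    trials[[i]] <- t(as.matrix(tab))
    info <- rbind(info, data.frame(subject = tr$subject,
                                   condition = tr$condition,
                                   trial = as.integer(tr$trial),
                                   stringsAsFactors = FALSE))
  }
  new("EmgStudy", trials = trials, fs = meta$fs, channelLabels = labels,
      info = info,
      branch = if (is.null(meta$branch)) "raw" else meta$branch,
      provenance = if (is.null(meta$provenance)) list() else meta$provenance)
}

#' Default pipeline configuration
#'
#' Returns the full stage-parameter list with the standard analysis
#' settings: 20-Hz high-pass envelope extraction, 1 s / 0.75 s Welch
#' windows, 0.5-70 Hz + 200 Hz MVAR conditioning, AIC order selection up to
#' `pMax`, K = 4 NMF with 10 restarts on 0-60 Hz, and the rmANOVA stage.
#' Override any entry via `...` (unknown names are rejected).
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    stages = c("preprocess", "coherence", "pdc", "unmix", "metrics",
               "stats", "synergies"),
    cutoffHz = 20,
    welchWindowS = 1, welchOverlapS = 0.75,
    mvarBand = c(0.5, 70), mvarFs = 200,
    pMax = 30, order = NULL, extended = FALSE,
    band = c(0, 60), k = 4, nRestarts = 10, tol = 1e-6, maxIter = 500,
    keepFraction = 0.30,
    varianceTarget = 0.90, synergyLowpass = 10, synergyFs = 100,
    alpha = 0.05,
    seed = 1L,
    outDir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "PipelineConfig"
  cfg
}

splitByGroup <- function(study) {
  grp <- paste(study@info$subject, study@info$condition, sep = "\r")
  idx <- split(seq_along(grp), factor(grp, levels = unique(grp)))
  lapply(idx, function(i)
    list(subject = study@info$subject[i[1L]],
         condition = study@info$condition[i[1L]],
         trials = study@trials[i]))
}

#' Run the end-to-end muscle-network pipeline
#'
#' Executes the enabled stages in dependency order on an EMG study:
#' envelope extraction, trial-pooled Welch coherence, MVAR/PDC, NMF
#' unmixing into per-component muscle networks, weighted graph metrics,
#' repeated-measures statistics, and time-domain synergy extraction. Stage
#' dependencies are validated before anything runs; every stage failure is
#' reported with the stage name. All randomness derives from `config$seed`,
#' so re-running with an identical configuration reproduces the outputs
#' exactly.
#'
#' @param study an [EmgStudy-class] (branch `"raw"`), or a path readable by
#'   [readEmgStudy()].
#' @param config a [pipelineConfig()].
#' @return list with the per-stage results (`envelopes`, `coherence`,
#'   `pdc`, `unmix`, `networks`, `metrics`, `anova`, `synergies`) and a
#'   `manifest` (config hash, seed, stages run). When `config$outDir` is
#'   set, tidy TSV outputs and a `manifest.yaml` are written there.
#' @export
runPipeline <- function(study, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(study)) study <- readEmgStudy(study)
  stopifnot(is(study, "EmgStudy"))
  stages <- config$stages
  deps <- list(coherence = "preprocess", pdc = "preprocess",
               unmix = c("coherence", "pdc"), metrics = "unmix",
               stats = "metrics", synergies = "preprocess")
  for (s in stages) {
    if (s == "unmix") {
      if (!any(deps$unmix %in% stages))
        stop("stage 'unmix' requires 'coherence' or 'pdc' to be enabled")
    } else if (!is.null(deps[[s]]) && !all(deps[[s]] %in% stages)) {
      stop("stage '", s, "' requires: ",
           paste(setdiff(deps[[s]], stages), collapse = ", "))
    }
  }
  res <- list(manifest = list(configHash = rlang::hash(unclass(config)),
                              seed = config$seed, stages = stages))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if ("preprocess" %in% stages) {
    res$envelopes <- stage("preprocess",
                           highpassRectify(study, config$cutoffHz))
  }
  groupsEnv <- if (!is.null(res$envelopes)) splitByGroup(res$envelopes)
  if ("coherence" %in% stages) {
    res$coherence <- stage("coherence", lapply(groupsEnv, function(g) {
      cohs <- lapply(g$trials, welchCoherency, fs = res$envelopes@fs,
                     windowS = config$welchWindowS,
                     overlapS = config$welchOverlapS,
                     channelLabels = res$envelopes@channelLabels)
      poolCoherence(cohs, subject = g$subject, condition = g$condition)
    }))
  }
  if ("pdc" %in% stages) {
    res$pdc <- stage("pdc", {
      cond <- conditionForMvar(res$envelopes, config$mvarBand, config$mvarFs)
      freqs <- seq(config$band[1L], config$band[2L], by = 0.5)
      lapply(splitByGroup(cond), function(g) {
        pdcs <- lapply(g$trials, function(x) {
          p <- if (is.null(config$order))
            selectOrderAic(x, config$pMax, cond@fs)$order
          else config$order
          fit <- fitMvar(x, p, cond@fs, cond@channelLabels)
          if (isTRUE(config$extended)) fit <- identifyInstantaneous(fit)
          modelPdc(fit, freqs)
        })
        poolPdc(pdcs, subject = g$subject, condition = g$condition)
      })
    })
  }
  if ("unmix" %in% stages) {
    res$unmix <- stage("unmix", {
      out <- list()
      for (kind in c("coherence", "pdc")) {
        if (is.null(res[[kind]])) next
        stk <- stackSpectra(res[[kind]], band = config$band)
        fac <- orderAndNormalize(unmixSpectra(
          stk, k = config$k, tol = config$tol, maxIter = config$maxIter,
          nRestarts = config$nRestarts, seed = config$seed))
        out[[kind]] <- fac
      }
      out
    })
    res$networks <- stage("unmix",
                          lapply(res$unmix, componentNetworks))
  }
  if ("metrics" %in% stages) {
    res$metrics <- stage("metrics",
                         do.call(rbind, lapply(res$networks, metricsTable)))
  }
  if ("stats" %in% stages) {
    res$anova <- stage("stats", {
      out <- list()
      for (dr in unique(res$metrics$directed)) {
        sub <- res$metrics[res$metrics$directed == dr, ]
        if (length(unique(sub$subject)) >= 3) {
          for (metric in c("CC", "GE", "BC")) {
            key <- paste0(if (dr) "directed" else "undirected", "_", metric)
            out[[key]] <- rmAnova(sub, value = metric, alpha = config$alpha)
          }
        }
      }
      out
    })
  }
  if ("synergies" %in% stages) {
    res$synergies <- stage("synergies", {
      sets <- lapply(groupsEnv, function(g) {
        env <- do.call(cbind, lapply(g$trials, conditionForSynergy,
                                     fs = res$envelopes@fs,
                                     lowpass = config$synergyLowpass,
                                     fsOut = config$synergyFs))
        nSyn <- estimateNSynergies(env, config$varianceTarget)$n
        extractSynergies(env, nSyn, seed = config$seed,
                         subject = g$subject, condition = g$condition,
                         channelLabels = res$envelopes@channelLabels)
      })
      k <- min(vapply(sets, function(s) ncol(s@basis), 1L))
      sets <- lapply(sets, function(s) {
        s@basis <- s@basis[, seq_len(k), drop = FALSE]
        s@activations <- s@activations[seq_len(k), , drop = FALSE]
        s
      })
      alignSynergies(sets)
    })
  }
  if (!is.null(config$outDir)) writePipelineOutputs(res, config)
  res
}

writePipelineOutputs <- function(res, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  put <- function(df, name) {
    f <- file.path(config$outDir, name)
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    artifacts <<- c(artifacts, name)
  }
  tidySpectra <- function(lst) {
    do.call(rbind, lapply(lst, function(s)
      data.frame(subject = s@subject, condition = s@condition,
                 from = rep(s@pairs[, "from"], ncol(s@values)),
                 to = rep(s@pairs[, "to"], ncol(s@values)),
                 frequency = rep(s@freqs, each = nrow(s@values)),
                 value = as.numeric(s@values))))
  }
  if (!is.null(res$coherence)) put(tidySpectra(res$coherence),
                                   "coherence.tsv")
  if (!is.null(res$pdc)) put(tidySpectra(res$pdc), "pdc.tsv")
  if (!is.null(res$unmix)) {
    for (kind in names(res$unmix)) {
      fac <- res$unmix[[kind]]
      put(data.frame(frequency = fac@freqs, fac@W),
          paste0("basis_", kind, ".tsv"))
      put(cbind(fac@index, t(fac@H)), paste0("loadings_", kind, ".tsv"))
    }
  }
  if (!is.null(res$metrics)) put(res$metrics, "metrics.tsv")
  if (!is.null(res$anova))
    put(do.call(rbind, lapply(names(res$anova), function(k)
      cbind(analysis = k, as.data.frame(res$anova[[k]])))), "anova.tsv")
  yaml::write_yaml(c(res$manifest, list(artifacts = as.list(artifacts))),
                   file.path(config$outDir, "manifest.yaml"))
}
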