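# Plain-text cohort container: one directory per patient holding
# samples.tsv (channels x time), channels.tsv (name/group/status),
# truth.tsv (channel, epileptic), meta.json (fs, patientId); outcomes.tsv
# and config.json at the cohort root.

#' Write a cohort to a plain-text container
#'
#' @param cohort a [SimCohort-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SimCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort@recordings)) {
    rec <- cohort@recordings[[i]]
    pdir <- file.path(dir, rec@patientId)
    dir.create(pdir, showWarnings = FALSE)
    data.table::fwrite(data.table::as.data.table(rec@samples),
                       file.path(pdir, "samples.tsv"), sep = "\t",
                       col.names = FALSE)
    info <- parseContacts(rec@channelNames)
    data.table::fwrite(
      data.frame(name = rec@channelNames, group = info$shaft,
                 status = ifelse(rec@badFlags, "bad", "good")),
      file.path(pdir, "channels.tsv"), sep = "\t")
    data.table::fwrite(
      data.frame(channel = rec@channelNames,
                 epileptic = as.integer(cohort@truth[[i]])),
      file.path(pdir, "truth.tsv"), sep = "\t")
    jsonlite::write_json(list(fs = rec@fs, patientId = rec@patientId),
                         file.path(pdir, "meta.json"), auto_unbox = TRUE)
  }
  if (nrow(cohort@outcomes))
    data.table::fwrite(cohort@outcomes, file.path(dir, "outcomes.tsv"),
                       sep = "\t")
  cfg <- cohort@config
  cfgList <- stats::setNames(
    lapply(slotNames(cfg), function(sn) slot(cfg, sn)), slotNames(cfg))
  jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from a plain-text container
#'
#' Reads the layout written by [writeCohort()]: per-patient sample
#' matrices with a channels table (BIDS-style name/status columns; rows
#' with status "bad" become bad flags) and truth table, plus cohort-level
#' outcomes.
#'
#' @param dir cohort directory.
#' @return a [SimCohort-class].
#' @export
readCohort <- function(dir) {
  if (!dir.exists(dir)) stopf("cohort directory not found: %s", dir)
  pdirs <- list.dirs(dir, recursive = FALSE)
  if (!length(pdirs)) stopf("no patient directories under %s", dir)
  recs <- list(); truths <- list()
  for (pdir in pdirs) {
    meta <- jsonlite::read_json(file.path(pdir, "meta.json"))
    chans <- data.table::fread(file.path(pdir, "channels.tsv"),
                               data.table = FALSE)
    mat <- as.matrix(data.table::fread(file.path(pdir, "samples.tsv"),
                                       header = FALSE, data.table = FALSE))
    rec <- RecordingSegment(mat, meta$fs, chans$name,
                            badFlags = chans$status == "bad",
                            patientId = meta$patientId)
    tr <- data.table::fread(file.path(pdir, "truth.tsv"),
                            data.table = FALSE)
    truth <- as.logical(tr$epileptic[match(chans$name, tr$channel)])
    recs[[length(recs) + 1L]] <- rec
    truths[[length(truths) + 1L]] <- truth
  }
  ocFile <- file.path(dir, "outcomes.tsv")
  outcomes <- if (file.exists(ocFile))
    data.table::fread(ocFile, data.table = FALSE)
  else data.frame(patient = character(), ilae = integer(),
                  engel = integer(), group = character())
  cfgFile <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfgFile)) {
    cl <- jsonlite::read_json(cfgFile, simplifyVector = TRUE)
    do.call(simConfig, cl[names(cl) %in% names(formals(simConfig))])
  } else simConfig(nPatients = length(recs))
  new("SimCohort", recordings = recs, truth = truths,
      outcomes = outcomes, config = cfg)
}

# Write per-patient tables, ROC points, summary and manifest for a run.
writeRunOutputs <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  put <- function(df, name) {
    path <- file.path(outDir, name)
    data.table::fwrite(df, path, sep = "\t")
    manifest <<- c(manifest, name)
  }
  for (p in run$patients) {
    if (!is.null(p$Y)) {
      y <- data.frame(channel = p$Y@channelNames, p$Y@Y)
      names(y)[-1L] <- paste0("t", seq_len(ncol(p$Y@Y)))
      put(y, sprintf("%s_Y.tsv", p$patientId))
    }
    z <- data.frame(channel = p$Z@channelNames, p$Z@Z)
    names(z)[-1L] <- p$Z@channelNames
    put(z, sprintf("%s_Z.tsv", p$patientId))
    put(data.frame(channel = names(p$s@s), strength = unname(p$s@s),
                   epileptic = as.integer(p$truth)),
        sprintf("%s_strength.tsv", p$patientId))
  }
  roc <- run$evaluation$pooled$all
  put(data.frame(threshold = roc@thresholds,
                 sensitivity = roc@sensitivity, fpr = roc@fpr),
      "roc_pooled.tsv")
  summ <- list(
    pooled = lapply(run$evaluation$pooled, function(r)
      list(auc = r@auc, ciLow = r@ciLow, ciHigh = r@ciHigh,
           nPos = r@nPos, nNeg = r@nNeg)),
    individual = run$evaluation$individual[c("aucs", "mean", "ciLow",
                                             "ciHigh")],
    anova = run$evaluation$anova,
    outcome = if (!is.null(run$evaluation$outcome))
      list(auc = run$evaluation$outcome$roc@auc,
           ciLow = run$evaluation$outcome$roc@ciLow,
           ciHigh = run$evaluation$outcome$roc@ciHigh,
           groupP = run$evaluation$outcome$groupP))
  jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- c(manifest, "summary.json")
  jsonlite::write_json(run$config[!vapply(run$config, is.null, TRUE)],
                       file.path(outDir, "config.json"), auto_unbox = TRUE)
  writeLines(c(manifest, "config.json", "manifest.txt"),
             file.path(outDir, "manifest.txt"))
  invisible(outDir)
}
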