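# Pipeline orchestration: ingest or simulate inputs, assign groups, bin
# residues per group with shared edges, estimate per-bin rates (with
# bootstrap SEs) and CAI, fit error-weighted lines, compare groups, and
# build fold-change curves -- all from one configuration with seeded
# determinism.

# Deterministic per-task seed derivation (keeps values below 2^31).
.taskSeed <- function(base, i) {
  as.integer((as.numeric(base) %% 65011 * 7919 + i * 104729) %% 2147483647)
}

#' Build a pipeline run configuration
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param simulate Optional list of \code{\link{simulationConfig}} arguments
#'   (excluding \code{seed}); when given, inputs are simulated.
#' @param inputs Optional list with \code{alignmentDir}, \code{rsaDir},
#'   \code{expressionFile}, \code{adaptivenessFile} (optional), \code{taxa}
#'   (taxon order; first = focal species).
#' @param fraction Grouping fraction (default 1/3: tertiles; 0.5 and 0.25
#'   reproduce the half/quarter controls).
#' @param edges RSA bin edges in percent (default ten 10\% bins).
#' @param bootstrapB Bootstrap replicates per bin (default 100).
#' @param treeNewick Estimation topology; defaults to the unrooted
#'   four-species yeast topology (branch lengths are starting values only).
#' @param analyses Subset of \code{c("dnds", "dn", "ds", "cai")}.
#' @param comparisons Subset of \code{c("core", "expression", "fourcell")}.
#' @param rateStarts Omega starting points for the ML fits.
#' @param piMethod Codon-frequency convention for the rate estimates:
#'   "F3x4" (default), "empirical" (recommended when codon usage differs
#'   strongly between compared groups), or "uniform".
#' @param bootRefit Bootstrap refit mode ("scale" or "full").
#' @return A list of class \code{runConfig}.
#' @export
runConfig <- function(seed, simulate = NULL, inputs = NULL,
                      fraction = 1 / 3, edges = seq(0, 100, by = 10),
                      bootstrapB = 100, treeNewick = NULL,
                      analyses = c("dnds", "dn", "ds", "cai"),
                      comparisons = c("core", "expression", "fourcell"),
                      rateStarts = c(0.1, 0.5, 1.5),
                      piMethod = c("F3x4", "empirical", "uniform"),
                      bootRefit = "scale") {
  if (is.null(simulate) && is.null(inputs))
    stop("either a simulate block or an inputs block is required")
  analyses <- match.arg(analyses, several.ok = TRUE)
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  piMethod <- match.arg(piMethod)
  cfg <- list(seed = as.integer(seed), simulate = simulate, inputs = inputs,
              fraction = fraction, edges = edges, bootstrapB = bootstrapB,
              treeNewick = treeNewick, analyses = analyses,
              comparisons = comparisons, rateStarts = rateStarts,
              piMethod = piMethod, bootRefit = bootRefit)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param file YAML path with the fields of \code{\link{runConfig}}.
#' @param seed Optional seed overriding the file's.
#' @return A \code{runConfig} list.
#' @export
readRunConfig <- function(file, seed = NULL) {
  y <- yaml::read_yaml(file)
  if (!is.null(seed)) y$seed <- seed
  do.call(runConfig, y)
}

.ingestInputs <- function(inputs) {
  files <- list.files(inputs$alignmentDir, pattern = "\\.fa(sta)?$",
                      full.names = TRUE)
  pids <- sub("\\.fa(sta)?$", "", basename(files))
  alignments <- lapply(files, readCodonAlignment, taxaOrder = inputs$taxa)
  names(alignments) <- pids
  rsa <- lapply(pids, function(p)
    readRsaTsv(file.path(inputs$rsaDir, paste0(p, ".tsv"))))
  names(rsa) <- pids
  expr <- utils::read.table(inputs$expressionFile, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  valueCol <- setdiff(names(expr), "protein_id")[1]
  names(expr)[names(expr) == valueCol] <- "value"
  tab <- if (!is.null(inputs$adaptivenessFile)) {
    utils::read.table(inputs$adaptivenessFile, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    relativeAdaptiveness(vapply(alignments, function(a)
      paste0(codons(a)[1L, ], collapse = ""), character(1)),
      referenceId = "input-focal-sequences")
  }
  proteins <- data.frame(protein_id = pids, stringsAsFactors = FALSE)
  proteins$expression <- expr$value[match(pids, expr$protein_id)]
  if (anyNA(proteins$expression))
    stop("expression proxy missing for: ",
         paste(pids[is.na(proteins$expression)], collapse = ", "))
  list(proteins = proteins, rsa = rsa, alignments = alignments,
       adaptiveness = tab)
}

# Group memberships for the requested comparison axes.
.groupMembers <- function(labels, comparisons) {
  g <- list()
  if ("core" %in% comparisons || "fourcell" %in% comparisons) {
    g$largeCore <- labels$protein_id[labels$core_class == "largeCore"]
    g$smallCore <- labels$protein_id[labels$core_class == "smallCore"]
  }
  if ("expression" %in% comparisons || "fourcell" %in% comparisons) {
    g$lowExpr <- labels$protein_id[labels$expr_class == "low"]
    g$highExpr <- labels$protein_id[labels$expr_class == "high"]
  }
  if ("fourcell" %in% comparisons) {
    for (co in c("largeCore", "smallCore")) for (ex in c("low", "high")) {
      nm <- paste0(co, "_", ex, "Expr")
      g[[nm]] <- labels$protein_id[labels$core_class == co &
                                     labels$expr_class == ex]
    }
  }
  g
}

#' Run the full residue-level analysis pipeline
#'
#' Stages, in order: ingest or simulate inputs; join codon alignments with
#' RSA into residue records; assign core-size and expression groups by
#' ranked fractions; bin gapless residues per group with shared edges;
#' estimate dN/dS, dN, dS (ML + codon-column bootstrap SEs) and CAI per
#' bin; fit error-weighted lines per group; compare slopes/intercepts
#' between groups; build fold-change curves with their null tests.
#' Unreliable bins degrade to warnings, never silent drops.
#'
#' @param config A \code{runConfig} (see \code{\link{runConfig}}).
#' @param outDir Optional directory: per-stage TSV outputs plus a JSON
#'   manifest with checksums are written there.
#' @return A run-report list: \code{groupLabels}, \code{binTable},
#'   \code{fits}, \code{comparisons}, \code{foldChanges},
#'   \code{warnings}, \code{provenance}.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "runConfig"))
  warnings <- character(0)
  note <- function(msg) warnings <<- c(warnings, msg)

  ## stage 1: inputs
  if (!is.null(config$simulate)) {
    simCfg <- do.call(simulationConfig, c(list(seed = config$seed),
                                          config$simulate))
    study <- simulateStudy(simCfg)
    data <- study[c("proteins", "rsa", "alignments", "adaptiveness")]
  } else {
    data <- .ingestInputs(config$inputs)
  }

  tree <- ape::read.tree(text = if (!is.null(config$treeNewick))
    config$treeNewick else
      paste0("((cerevisiae:0.1,paradoxus:0.1):0.05,",
             "mikatae:0.15,bayanus:0.15);"))

  ## stage 2: residue records
  records <- do.call(rbind, lapply(names(data$alignments), function(pid)
    mapCodonsToStructure(data$alignments[[pid]], data$rsa[[pid]], pid)))
  nDropped <- sum(!records$gapless)
  if (nDropped > 0)
    note(paste0(nDropped, " residue record(s) not gapless; excluded from bins"))

  ## stage 3: groups
  avg <- averageRsa(records)
  prot <- merge(data$proteins, avg, by = "protein_id")
  labels <- assignGroups(prot, fraction = config$fraction)
  members <- .groupMembers(labels, config$comparisons)

  ## stage 4-6: per-group binning, rates, CAI
  gapless <- records[records$gapless, , drop = FALSE]
  binRows <- list()
  fits <- list()
  taskCounter <- 0L
  for (g in names(members)) {
    rec <- gapless[gapless$protein_id %in% members[[g]], , drop = FALSE]
    bins <- binResidues(rec, edges = config$edges)
    for (b in bins) {
      taskCounter <- taskCounter + 1L
      if (nrow(b$records) == 0L) {
        note(sprintf("group %s bin %d empty; dropped from fit", g, b$bin))
        next
      }
      ba <- concatenateBinAlignment(b$records, b$bin, b$lo, b$hi, b$x)
      pt <- tryCatch(suppressWarnings(
        estimateRatesML(ba, tree, starts = config$rateStarts,
                        piMethod = config$piMethod)),
        error = function(e) NULL)
      if (is.null(pt)) {
        note(sprintf("group %s bin %d: rate estimation failed", g, b$bin))
        next
      }
      est <- suppressWarnings(
        bootstrapSE(ba, tree, B = config$bootstrapB,
                    seed = .taskSeed(config$seed, taskCounter),
                    pointEstimate = pt, refit = config$bootRefit))
      if (!est@defined)
        note(sprintf("group %s bin %d: dN/dS undefined (no synonymous variation)",
                     g, b$bin))
      if (!est@seReliable)
        note(sprintf("group %s bin %d: bootstrap SE unreliable", g, b$bin))
      row <- data.frame(group = g, bin_index = b$bin, x_rsa = b$x,
                        n_codons = est@nCodons,
                        dnds = est@dnds, se_dnds = est@seDnds,
                        dn = est@dn, se_dn = est@seDn,
                        ds = est@ds, se_ds = est@seDs,
                        lnL = est@logLik, converged = est@converged,
                        se_reliable = est@seReliable,
                        stringsAsFactors = FALSE)
      if ("cai" %in% config$analyses) {
        ci <- caiWithSE(ba, data$adaptiveness, B = config$bootstrapB,
                        seed = .taskSeed(config$seed, taskCounter) + 1L)
        row$cai <- ci$cai
        row$se_cai <- ci$se
      }
      binRows[[length(binRows) + 1L]] <- row
    }
  }
  binTable <- do.call(rbind, binRows)

  ## stage 7: per-group dN/dS-vs-RSA line fits (bins with unreliable
  ## bootstrap errors or boundary estimates are excluded and logged)
  for (g in names(members)) {
    bt <- binTable[binTable$group == g & binTable$se_reliable, , drop = FALSE]
    nBad <- sum(binTable$group == g & !binTable$se_reliable)
    if (nBad > 0)
      note(sprintf("group %s: %d bin(s) with unreliable errors excluded from fit",
                   g, nBad))
    fits[[g]] <- tryCatch(
      suppressMessages(weightedLineFit(bt$x_rsa, bt$dnds, bt$se_dnds)),
      error = function(e) {
        note(sprintf("group %s: line fit failed (%s)", g, conditionMessage(e)))
        NULL
      })
  }

  ## stage 8: comparisons and fold changes
  comparisons <- list()
  addCmp <- function(x) comparisons[[length(comparisons) + 1L]] <<- x
  cmpPair <- function(a, b, analysis) {
    if (is.null(fits[[a]]) || is.null(fits[[b]])) return(invisible())
    addCmp(compareLineParams(fits[[a]], fits[[b]], "slope", a, b, analysis))
    addCmp(compareLineParams(fits[[a]], fits[[b]], "intercept", a, b, analysis))
  }
  if ("core" %in% config$comparisons) cmpPair("largeCore", "smallCore", "core")
  if ("expression" %in% config$comparisons)
    cmpPair("lowExpr", "highExpr", "expression")
  if ("fourcell" %in% config$comparisons) {
    cells <- c("largeCore_lowExpr", "largeCore_highExpr",
               "smallCore_lowExpr", "smallCore_highExpr")
    combs <- utils::combn(cells, 2)
    for (i in seq_len(ncol(combs)))
      cmpPair(combs[1, i], combs[2, i], "fourcell")
  }

  axes <- list(core = c("largeCore", "smallCore"),
               expression = c("lowExpr", "highExpr"))
  measures <- intersect(config$analyses, c("dnds", "dn", "ds", "cai"))
  foldChanges <- list()
  for (ax in intersect(names(axes), config$comparisons)) {
    for (ms in measures) {
      a <- axes[[ax]][1]; b <- axes[[ax]][2]
      bta <- binTable[binTable$group == a, , drop = FALSE]
      btb <- binTable[binTable$group == b, , drop = FALSE]
      common <- intersect(bta$bin_index, btb$bin_index)
      bta <- bta[match(common, bta$bin_index), ]
      btb <- btb[match(common, btb$bin_index), ]
      ycol <- ms; scol <- paste0("se_", ms)
      # shared bins, but per-group mean-RSA x values differ slightly; use
      # the numerator group's x for the curve
      sa <- data.frame(x = bta$x_rsa, y = bta[[ycol]], sigma = bta[[scol]])
      sb <- data.frame(x = bta$x_rsa, y = btb[[ycol]], sigma = btb[[scol]])
      if (ms == "dnds") {   # boundary/degenerate-error bins carry no weight
        sa$sigma[!bta$se_reliable] <- NA_real_
        sb$sigma[!btb$se_reliable] <- NA_real_
      }
      fc <- tryCatch(suppressMessages(foldChangeCurve(sa, sb)),
                     error = function(e) NULL)
      if (is.null(fc) || nrow(fc) < 3) {
        note(sprintf("fold change %s/%s (%s): too few defined bins", a, b, ms))
        next
      }
      ft <- tryCatch(suppressMessages(foldChangeTests(
        fc, analysis = paste0(ax, ":", ms))), error = function(e) NULL)
      foldChanges[[paste0(ax, ".", ms)]] <-
        list(axis = ax, measure = ms, curve = fc,
             fit = ft$fit, tests = ft$tests)
    }
  }

  ## null tests on each group's own line (slope = 0)
  for (g in names(fits)) {
    if (is.null(fits[[g]])) next
    nt <- testParamNull(fits[[g]], "slope", 0)
    nt$analysis <- "slopeNull"; nt$group_A <- g
    addCmp(nt)
  }
  comparisons <- do.call(rbind, comparisons)

  report <- list(groupLabels = labels, binTable = binTable, fits = fits,
                 comparisons = comparisons, foldChanges = foldChanges,
                 warnings = warnings,
                 provenance = list(seed = config$seed,
                                   fraction = config$fraction,
                                   edges = config$edges,
                                   bootstrapB = config$bootstrapB,
                                   packageVersion =
                                     as.character(utils::packageVersion("rsaRates"))))
  if (!is.null(outDir)) writeRunReport(report, outDir)
  report
}

#' Write a run report's tables and a checksum manifest
#'
#' @param report Result of \code{\link{runPipeline}}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
writeRunReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    wt(report$groupLabels, "group_labels.tsv"),
    wt(report$binTable, "bin_estimates.tsv"),
    wt(report$comparisons, "comparisons.tsv"))
  fitRows <- do.call(rbind, lapply(names(report$fits), function(g) {
    f <- report$fits[[g]]
    if (is.null(f)) return(NULL)
    data.frame(group = g, slope = f@slope, intercept = f@intercept,
               se_slope = f@seSlope, se_intercept = f@seIntercept,
               n = f@n, chisq = f@chisq, stringsAsFactors = FALSE)
  }))
  if (!is.null(fitRows)) files <- c(files, wt(fitRows, "line_fits.tsv"))
  for (nm in names(report$foldChanges)) {
    fc <- report$foldChanges[[nm]]
    files <- c(files, wt(fc$curve, paste0("foldchange_", nm, ".tsv")),
               wt(fc$tests, paste0("foldchange_", nm, "_tests.tsv")))
  }
  if (length(report$warnings))
    writeLines(report$warnings, file.path(dir, "warnings.txt"))
  manifest <- list(
    provenance = report$provenance,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
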