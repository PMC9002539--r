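#' @include AllClasses.R io.R
NULL

.defaultProteinNames <- function(n = 17L) {
  nm <- c("alpha_amylase", "MUC5B", "MUC7", "Cyst_SN", "Cyst_S1", "Cyst_S2",
          "Cyst_SA", "Cyst_total", "Histatin_1", "Histatin_3", "Histatin_5_6",
          "aPRP_1", "aPRP_2", "bPRP_1", "bPRP_2", "bPRP_3", "Statherin",
          "Lactoferrin", "Lysozyme", "Total_protein")
  nm[seq_len(n)]
}

.defaultSensoryNames <- function(n = 7L) {
  c("sweetness", "bitterness", "sourness", "astringency", "thickness",
    "cranberry_flavor", "overall_flavor")[seq_len(n)]
}

#' Construct a synthetic study scenario
#'
#' Defaults emulate the study design the package targets: 10 NT + 10 ST
#' subjects, two timepoints with one ST post-intervention sample missing,
#' 300 ASVs of which 60 are prevalent and organised into 13 co-abundance
#' guilds, multinomial sampling at 5,000 reads/sample (desk-scale depth), a
#' baseline log-scale shift of 2.5 applied to one guild's latent factor in
#' ST samples, an intervention shift of 2.5 applied to another guild in NT
#' post-intervention samples only, 17 protein and 7 sensory variables with
#' subject-level random effects, and planted protein/guild-factor couplings
#' that are denser in ST than NT.
#'
#' @param nSubjectsPerGroup,nAsvs,nPrevalent,nGuilds,readDepth,seed see slots
#'   of [SyntheticScenario-class].
#' @param guildEffectBaseline,interventionEffectNT planted log-scale factor
#'   shifts (default 2.5 each; sized so the planted contrasts are detectable by distance-based tests at 10 subjects per group).
#' @param loadingScale multiplier on ASV loadings (default 1; used by
#'   recovery sweeps).
#' @param subjectSd subject-level factor offset sd (default 0.5).
#' @param asvNoiseSd ASV-level log-abundance noise sd (default 0.3).
#' @param dropout data.frame(subject_id, timepoint) of omitted samples;
#'   default: the last ST subject's post sample.
#' @param nProteins,nSensory phenotype widths (defaults 17 and 7).
#' @param proteinCoupling planted protein/guild coupling strength (default 2).
#' @return a validated [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nSubjectsPerGroup = 10L, nAsvs = 300L,
                              nPrevalent = 60L, nGuilds = 13L,
                              readDepth = 5000L, guildEffectBaseline = 2.5,
                              interventionEffectNT = 2.5, loadingScale = 1,
                              subjectSd = 0.5, asvNoiseSd = 0.3,
                              dropout = NULL, nProteins = 17L, nSensory = 7L,
                              proteinCoupling = 2, seed = 1L) {
  if (is.null(dropout)) {
    lastST <- sprintf("S%02d", 2L * nSubjectsPerGroup)
    dropout <- data.frame(subject_id = lastST, timepoint = "post")
  }
  methods::new("SyntheticScenario",
    nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
    nAsvs = as.integer(nAsvs), nPrevalent = as.integer(nPrevalent),
    nGuilds = as.integer(nGuilds), readDepth = as.integer(readDepth),
    guildEffectBaseline = guildEffectBaseline,
    interventionEffectNT = interventionEffectNT,
    loadingScale = loadingScale, subjectSd = subjectSd,
    asvNoiseSd = asvNoiseSd, dropout = dropout,
    nProteins = as.integer(nProteins), nSensory = as.integer(nSensory),
    proteinCoupling = proteinCoupling, seed = as.integer(seed))
}

#' Random rooted bifurcating phylogeny over ASV tips
#'
#' Exponential(1) branch lengths; tips labelled ASV_1..ASV_n. A strictly
#' bifurcating rooted tree over n tips has n - 1 internal nodes.
#'
#' @param nAsvs number of tips (>= 2).
#' @param seed integer seed.
#' @return rooted \code{ape::phylo}.
#' @export
generateTree <- function(nAsvs, seed = 1L) {
  if (nAsvs < 2L) stop("need at least 2 tips")
  set.seed(as.integer(seed))
  tr <- ape::rtree(nAsvs, rooted = TRUE, br = stats::rexp)
  tr$tip.label <- paste0("ASV_", seq_len(nAsvs))
  tr
}

.studyDesign <- function(scenario) {
  nG <- scenario@nSubjectsPerGroup
  subjects <- sprintf("S%02d", seq_len(2L * nG))
  taster <- rep(c("NT", "ST"), each = nG)
  age <- round(stats::rnorm(2L * nG, 21.6, 2))
  bmi <- round(stats::rnorm(2L * nG, 24.4, 2), 1)
  gender <- sample(rep(c("F", "M"), length.out = 2L * nG))
  des <- expand.grid(timepoint = c("pre", "post"), subject_id = subjects,
                     stringsAsFactors = FALSE)[, c(2L, 1L)]
  des$taster_status <- taster[match(des$subject_id, subjects)]
  des$age <- age[match(des$subject_id, subjects)]
  des$gender <- gender[match(des$subject_id, subjects)]
  des$bmi <- bmi[match(des$subject_id, subjects)]
  drop <- paste(scenario@dropout$subject_id, scenario@dropout$timepoint)
  des <- des[!(paste(des$subject_id, des$timepoint) %in% drop), ]
  des$sample_id <- paste(des$subject_id, des$timepoint, sep = "_")
  rownames(des) <- des$sample_id
  des[, c("sample_id", "subject_id", "taster_status", "timepoint",
          "age", "gender", "bmi")]
}

#' Generate a synthetic count table with planted guild structure
#'
#' Generative model, per sample s: each guild g carries a latent factor
#' \eqn{f_{g,s} \sim N(\mu_{g,s} + u_{g,subject(s)}, 1)} where the mean
#' encodes the planted effects (the ST baseline shift on the most-abundant
#' guild at both timepoints, the NT-only post-intervention shift on the
#' second-most-abundant guild) and \eqn{u} is a subject-level offset
#' (sd \code{subjectSd}). Log expected abundance of prevalent ASV i is
#' \eqn{base_i + \lambda_i f_{guild(i),s} + \epsilon} with loadings
#' \eqn{\lambda_i \sim U[0.5, 1]} (times \code{loadingScale}) and
#' \eqn{\epsilon \sim N(0, asvNoiseSd)}. Non-prevalent ASVs get low base
#' values and independent noise. Counts are drawn multinomially at
#' \code{readDepth} per sample, so every row sums exactly to the depth.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return list: \code{counts} (samples x ASVs integer matrix), \code{design}
#'   (data.frame), \code{truth} (guild map, effect guild indices, factor
#'   matrices, loadings, seed).
#' @export
generateCounts <- function(scenario) {
  methods::validObject(scenario)
  set.seed(scenario@seed)
  design <- .studyDesign(scenario)
  nS <- nrow(design)
  nA <- scenario@nAsvs
  nP <- scenario@nPrevalent
  G <- scenario@nGuilds

  guildOf <- sort(rep_len(seq_len(G), nP))
  names(guildOf) <- paste0("ASV_", seq_len(nP))
  basePrev <- stats::rnorm(nP, 0, 0.3)
  # sparse tail: low median abundance but heavy per-sample dispersion, so the
  # non-prevalent ASVs stay below 50% prevalence yet still carry ~10% of reads
  baseRare <- stats::rnorm(nA - nP, -8, 1)
  lambda <- stats::runif(nP, 0.5, 1) * scenario@loadingScale

  # planted-effect guilds: largest and second-largest expected base abundance
  gTot <- tapply(exp(basePrev), guildOf, sum)
  ord <- order(gTot, decreasing = TRUE)
  gBase <- as.integer(names(gTot)[ord[1L]])
  gInt <- as.integer(names(gTot)[ord[2L]])

  subjects <- unique(design$subject_id)
  u <- matrix(stats::rnorm(length(subjects) * G, 0, scenario@subjectSd),
              length(subjects), G, dimnames = list(subjects, NULL))

  counts <- matrix(0L, nS, nA,
                   dimnames = list(design$sample_id, paste0("ASV_", seq_len(nA))))
  f <- matrix(0, nS, G, dimnames = list(design$sample_id, paste0("G", seq_len(G))))
  for (s in seq_len(nS)) {
    mu <- u[design$subject_id[s], ]
    if (design$taster_status[s] == "ST") {
      mu[gBase] <- mu[gBase] + scenario@guildEffectBaseline
    }
    if (design$taster_status[s] == "NT" && design$timepoint[s] == "post") {
      mu[gInt] <- mu[gInt] + scenario@interventionEffectNT
    }
    f[s, ] <- stats::rnorm(G, mu, 1)
    logPrev <- basePrev + lambda * f[s, guildOf] +
      stats::rnorm(nP, 0, scenario@asvNoiseSd)
    logRare <- baseRare + stats::rnorm(nA - nP, 0, 2)
    p <- exp(c(logPrev, logRare))
    counts[s, ] <- stats::rmultinom(1L, scenario@readDepth, p / sum(p))[, 1L]
  }
  list(counts = counts, design = design,
       truth = list(guild = guildOf, baseline_guild = gBase,
                    intervention_guild = gInt, factors = f,
                    subject_offsets = u, loadings = lambda,
                    base_prevalent = basePrev,
                    effects = c(baseline = scenario@guildEffectBaseline,
                                intervention = scenario@interventionEffectNT),
                    seed = scenario@seed))
}

.defaultProteinLinks <- function(scenario) {
  pn <- .defaultProteinNames(scenario@nProteins)
  G <- scenario@nGuilds
  # six ST couplings (PRP-type proteins vs mid-rank guilds), one NT coupling
  # (MUC7), mirroring a denser ST network; guilds indexed 1..G cyclically.
  gidx <- function(i) ((i - 1L) %% G) + 1L
  stVars <- pn[pmin(c(12L, 13L, 14L, 15L, 16L, 4L, 9L, 17L, 6L), length(pn))]
  st <- data.frame(
    variable = stVars,
    guild = vapply(c(3L, 4L, 6L, 7L, 8L, 12L, 5L, 9L, 10L), gidx, 1L),
    group = "ST", table = "proteins", stringsAsFactors = FALSE)
  nt <- data.frame(variable = pn[3L], guild = gidx(11L), group = "NT",
                   table = "proteins", stringsAsFactors = FALSE)
  ntSens <- data.frame(variable = "bitterness", guild = gidx(11L),
                       group = "NT", table = "sensory", stringsAsFactors = FALSE)
  rbind(st, nt, ntSens)
}

#' Generate protein and sensory phenotype tables
#'
#' Each variable is subject random intercept (sd \code{subjectIntSd}) +
#' planted treatment effect + planted guild-factor coupling + noise. Two
#' protein variables (alpha_amylase, MUC5B) are planted to decrease post-
#' intervention and two (Cyst_SN, Cyst_S2) to increase, mirroring the
#' direction of the salivary-protein findings the generator emulates.
#' Couplings add \code{proteinCoupling * f[g, sample]} for samples of the
#' linked taster group, enabling network-recovery tests.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param design design data.frame from [generateCounts].
#' @param factors samples-by-guilds latent factor matrix from the truth
#'   ledger (NULL disables couplings).
#' @param links data.frame(variable, guild, group, table) of planted
#'   couplings; default [.defaultProteinLinks] pattern (denser in ST).
#' @param treatmentEffect absolute post-intervention shift for the four
#'   planted proteins (default 1).
#' @param subjectIntSd,noiseSd random-intercept and residual sds (1 and 0.5).
#' @return list(proteins, sensory) of samples-by-variables data.frames, with
#'   attribute \code{"links"} on the list.
#' @export
generatePhenotypes <- function(scenario, design, factors = NULL, links = NULL,
                               treatmentEffect = 1, subjectIntSd = 1,
                               noiseSd = 0.5) {
  set.seed(scenario@seed + 1000L)
  if (is.null(links)) links <- .defaultProteinLinks(scenario)
  pn <- .defaultProteinNames(scenario@nProteins)
  sn <- .defaultSensoryNames(scenario@nSensory)
  subjects <- unique(design$subject_id)
  post <- design$timepoint == "post"

  mk <- function(vars, tableName) {
    out <- matrix(0, nrow(design), length(vars),
                  dimnames = list(design$sample_id, vars))
    for (j in seq_along(vars)) {
      intc <- stats::setNames(stats::rnorm(length(subjects), 0, subjectIntSd),
                              subjects)
      val <- intc[design$subject_id] + stats::rnorm(nrow(design), 0, noiseSd)
      if (tableName == "proteins") {
        if (vars[j] %in% c("alpha_amylase", "MUC5B")) val[post] <- val[post] - treatmentEffect
        if (vars[j] %in% c("Cyst_SN", "Cyst_S2")) val[post] <- val[post] + treatmentEffect
      }
      lk <- links[links$variable == vars[j] & links$table == tableName, , drop = FALSE]
      if (nrow(lk) && !is.null(factors)) {
        for (i in seq_len(nrow(lk))) {
          sel <- design$taster_status == lk$group[i]
          val[sel] <- val[sel] +
            scenario@proteinCoupling * factors[design$sample_id[sel], lk$guild[i]]
        }
      }
      out[, j] <- val
    }
    as.data.frame(out)
  }
  res <- list(proteins = mk(pn, "proteins"), sensory = mk(sn, "sensory"))
  attr(res, "links") <- links
  res
}

#' Simulate a full synthetic study
#'
#' Runs [generateTree], [generateCounts] and [generatePhenotypes] under one
#' scenario and bundles the result.
#'
#' @param scenario a [SyntheticScenario-class] (default [syntheticScenario()]).
#' @return list: \code{experiment} ([AsvExperiment-class] with tree and
#'   design), \code{proteins}, \code{sensory} (data.frames), \code{truth}
#'   (planted-effect ledger incl. phenotype links).
#' @export
simulateStudy <- function(scenario = syntheticScenario()) {
  tree <- generateTree(scenario@nAsvs, seed = scenario@seed + 500L)
  gc <- generateCounts(scenario)
  ph <- generatePhenotypes(scenario, gc$design, factors = gc$truth$factors)
  gc$truth$links <- attr(ph, "links")
  exp <- AsvExperiment(gc$counts, design = gc$design, tree = tree)
  list(experiment = exp, proteins = ph$proteins, sensory = ph$sensory,
       truth = gc$truth)
}

#' Write a simulated study to a directory
#'
#' Writes counts.tsv, tree.nwk, design.tsv, proteins.tsv, sensory.tsv and
#' truth.json.
#'
#' @param sim result of [simulateStudy].
#' @param dir output directory (created if needed).
#' @export
writeSimulatedStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountTable(asvCounts(sim$experiment), file.path(dir, "counts.tsv"))
  writeNewickTree(asvTree(sim$experiment), file.path(dir, "tree.nwk"))
  writeDesign(sampleData(sim$experiment), file.path(dir, "design.tsv"))
  writePhenotypeTable(sim$proteins, file.path(dir, "proteins.tsv"))
  writePhenotypeTable(sim$sensory, file.path(dir, "sensory.tsv"))
  truth <- sim$truth
  truth$factors <- NULL; truth$subject_offsets <- NULL  # matrices stay in R
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
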