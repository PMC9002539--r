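#' @include synthetic.R diversity.R ordination.R guilds.R associations.R
NULL

.configDefaults <- function() {
  list(
    input_dir = NULL,            # directory with counts.tsv/tree.nwk/... ;
                                 # NULL -> simulate the default scenario
    scenario = list(),           # overrides for syntheticScenario()
    rarefaction_depth = NULL,    # NULL -> 76000 for file input, scenario
                                 # depth for synthetic input
    prevalence_threshold = 0.5,  # strict
    min_guild_size = 2L,
    r_threshold = NULL,          # NULL -> 1/sqrt(df), the estimator null scale
    linkage = "average",
    q_threshold = 0.25,
    permutations = 9999L,
    distance = "weighted_unifrac",  # metric for the PERMANOVA contrasts
    seed = 1L,
    out_dir = "oralguilds_out"
  )
}

#' Parse a YAML pipeline configuration
#'
#' Unknown keys are an error (never silently ignored); missing keys take
#' defaults; basic range checks are applied.
#'
#' @param path YAML file (an empty file yields all defaults).
#' @return named list (class "oralguilds_config").
#' @export
parseConfig <- function(path) {
  raw <- if (is.null(path)) list() else yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  defs <- .configDefaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, raw, keep.null = TRUE)
  if (!is.null(cfg$prevalence_threshold) &&
      (cfg$prevalence_threshold <= 0 || cfg$prevalence_threshold >= 1))
    stop("prevalence_threshold out of range (0,1): ", cfg$prevalence_threshold)
  if (cfg$q_threshold < 0 || cfg$q_threshold > 1)
    stop("q_threshold out of range [0,1]: ", cfg$q_threshold)
  if (cfg$permutations < 1) stop("permutations must be >= 1")
  cfg$permutations <- as.integer(cfg$permutations)
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_guild_size <- as.integer(cfg$min_guild_size)
  class(cfg) <- c("oralguilds_config", "list")
  cfg
}

#' Serialise a config canonically
#'
#' Keys are emitted in the fixed default order, so
#' \code{dumpConfig(parseConfig(f))} is a normal form.
#'
#' @param cfg config list from [parseConfig].
#' @param path optional file; otherwise the YAML string is returned.
#' @export
dumpConfig <- function(cfg, path = NULL) {
  ordered <- cfg[names(.configDefaults())]
  txt <- yaml::as.yaml(ordered)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(path)) }
  txt
}

.loadInputs <- function(cfg) {
  if (is.null(cfg$input_dir)) {
    scArgs <- cfg$scenario[setdiff(names(cfg$scenario), "seed")]
    sc <- do.call(syntheticScenario, c(scArgs, list(seed = cfg$seed)))
    sim <- simulateStudy(sc)
    depth <- if (is.null(cfg$rarefaction_depth)) sc@readDepth else cfg$rarefaction_depth
    c(sim, list(depth = depth))
  } else {
    counts <- readCountTable(file.path(cfg$input_dir, "counts.tsv"))
    tree <- readNewickTree(file.path(cfg$input_dir, "tree.nwk"))
    design <- readDesign(file.path(cfg$input_dir, "design.tsv"))
    proteins <- readPhenotypeTable(file.path(cfg$input_dir, "proteins.tsv"))
    sensory <- readPhenotypeTable(file.path(cfg$input_dir, "sensory.tsv"))
    depth <- if (is.null(cfg$rarefaction_depth)) 76000L else cfg$rarefaction_depth
    list(experiment = AsvExperiment(counts, design = design, tree = tree),
         proteins = proteins, sensory = sensory, truth = NULL, depth = depth)
  }
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] %.2fs", name, as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full analysis pipeline
#'
#' simulate/load -> rarefy -> alpha diversity -> UniFrac -> PCoA + adjusted
#' PCoA -> four PERMANOVA contrasts (NT vs ST at pre and at post, free
#' permutations over the one-sample-per-subject subsets; pre vs post within
#' NT and within ST, subject-stratified permutations) -> prevalence filter
#' and guild construction -> guild group comparisons -> guild/protein/sensory
#' networks for each taster group -> JSON run report.
#'
#' All randomness derives from \code{cfg$seed}. Artifacts are written under
#' \code{cfg$out_dir}.
#'
#' @param cfg config from [parseConfig] (or NULL for all defaults).
#' @return invisibly, the run report list.
#' @export
runPipeline <- function(cfg = NULL) {
  if (is.null(cfg)) cfg <- parseConfig(NULL)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("OralGuilds")),
                 r_version = R.version.string,
                 seed = cfg$seed,
                 config = unclass(cfg)[setdiff(names(cfg), "out_dir")])

  inputs <- .stage("load", .loadInputs(cfg))
  exp <- inputs$experiment
  counts <- .stage("rarefy", rarefy(asvCounts(exp), inputs$depth,
                                    seed = cfg$seed + 1L))
  design <- sampleData(exp)[rownames(counts), , drop = FALSE]
  tree <- asvTree(exp)

  alpha <- .stage("alpha", alphaDiversity(counts, tree = tree))
  utils::write.table(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dW <- .stage("unifrac_weighted", uniFrac(counts, tree, weighted = TRUE))
  dU <- .stage("unifrac_unweighted", uniFrac(counts, tree, weighted = FALSE))
  writeDistanceMatrix(dW, file.path(cfg$out_dir, "weighted_unifrac.tsv"))
  writeDistanceMatrix(dU, file.path(cfg$out_dir, "unweighted_unifrac.tsv"))
  dist <- if (cfg$distance == "weighted_unifrac") dW else dU

  ord <- .stage("pcoa", pcoaOrdination(dist))
  aord <- .stage("apcoa", apcoaOrdination(dist,
                   data.frame(subject = design$subject_id)))
  coords <- ordCoordinates(ord)
  utils::write.table(
    data.frame(sample_id = rep(rownames(coords), ncol(coords)),
               axis = rep(colnames(coords), each = nrow(coords)),
               value = as.vector(coords)),
    file.path(cfg$out_dir, "pcoa_coordinates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  report$pcoa <- list(
    proportion_explained = utils::head(propExplained(ord), 5L),
    first_two_axes_pct = 100 * sum(utils::head(propExplained(ord), 2L)))

  ids <- rownames(counts)
  contrasts <- list(
    nt_vs_st_pre = list(sel = design$timepoint == "pre",
                        groups = "taster_status", scheme = "free"),
    nt_vs_st_post = list(sel = design$timepoint == "post",
                         groups = "taster_status", scheme = "free"),
    pre_vs_post_nt = list(sel = design$taster_status == "NT",
                          groups = "timepoint", scheme = "stratified_by_subject"),
    pre_vs_post_st = list(sel = design$taster_status == "ST",
                          groups = "timepoint", scheme = "stratified_by_subject"))
  perma <- list()
  dm <- as.matrix(dist)
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    sub <- ids[ct$sel]
    res <- .stage(paste0("permanova_", nm), permanova(
      dm[sub, sub], design[sub, ct$groups],
      scheme = ct$scheme,
      strata = if (ct$scheme == "stratified_by_subject") design[sub, "subject_id"],
      nPermutations = cfg$permutations, seed = cfg$seed + 2L))
    perma[[nm]] <- res[c("pseudo_F", "p_value", "R2", "n_permutations", "scheme")]
  }
  report$permanova <- perma

  pf <- .stage("prevalence", prevalenceFilter(counts, cfg$prevalence_threshold))
  prevIds <- colnames(pf$table)
  relab <- toRelative(counts, "none")
  trans <- toRelative(counts, "arcsine_sqrt", subset = prevIds)
  assignment <- .stage("guilds", guildCluster(
    trans, design$subject_id, minGuildSize = cfg$min_guild_size,
    rThreshold = cfg$r_threshold, linkage = cfg$linkage))
  writeGuildAssignment(assignment, file.path(cfg$out_dir, "guilds.tsv"))
  gtable <- guildAbundance(relab, assignment)
  report$guilds <- list(
    n_prevalent = length(prevIds),
    prevalent_read_share = sum(counts[, prevIds]) / sum(counts),
    n_guilds = nGuilds(assignment),
    n_unassigned = length(guildUnassigned(assignment)))

  gcomp <- .stage("guild_comparisons", rbind(
    cbind(contrast = "NT_vs_ST_pre",
          compareGuilds(gtable, design, "NT_vs_ST", timepoint = "pre")),
    cbind(contrast = "NT_vs_ST_post",
          compareGuilds(gtable, design, "NT_vs_ST", timepoint = "post")),
    cbind(contrast = "pre_vs_post_NT",
          compareGuilds(gtable, design, "pre_vs_post", group = "NT")),
    cbind(contrast = "pre_vs_post_ST",
          compareGuilds(gtable, design, "pre_vs_post", group = "ST"))))
  utils::write.table(gcomp, file.path(cfg$out_dir, "guild_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nets <- list()
  for (grp in c("NT", "ST")) {
    net <- .stage(paste0("network_", grp), suppressMessages(buildNetwork(
      gtable, inputs$proteins, inputs$sensory, design, group = grp,
      qThreshold = cfg$q_threshold)))
    writeNetwork(net, file.path(cfg$out_dir, paste0("network_", grp)))
    nets[[grp]] <- networkSummary(net)
  }
  report$networks <- nets

  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
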