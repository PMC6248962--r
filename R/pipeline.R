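write_tsv <- function(x, path, rn = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rn, col.names = !is.null(colnames(x)) || is.data.frame(x))
  path
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full dominant-marker analysis and write a report bundle
#'
#' One call reproduces every stage of the pipeline on a band matrix (plus
#' optional GPS table): per-primer informativeness, per-population
#' diversity, AMOVA with permutation-tested Phi-ST, pairwise Phi-ST and Nei
#' distances (combined lower/upper-triangle table), diversity partitioning
#' (GST, G'ST, Jost's D) with the island-model gene-flow estimate from the
#' AMOVA Phi-ST, PCoA of the pairwise Phi-ST matrix, Mantel
#' isolation-by-distance against Slatkin-linearized Phi-ST, and replicate
#' admixture runs with the Evanno delta-K table and per-population
#' membership summary. Every stochastic stage is seeded deterministically
#' from `seed` (stage offsets recorded in the manifest), so a rerun with the
#' same seed is byte-identical.
#'
#' @param m a [marker_matrix].
#' @param geo optional GPS data.frame (`sample`, `lat`, `lon`).
#' @param out_dir output directory (created if needed).
#' @param model frequency model for diversity statistics.
#' @param n_perm_amova,n_perm_mantel permutation counts.
#' @param K_range,n_runs,burn_in,reps admixture run grid and MCMC lengths.
#' @param pcoa_dialect centering dialect for the report's PCoA (the raw
#'   Gower centering is the population-ordination convention; see [pcoa()]).
#' @param seed master integer seed.
#' @param digits reported decimals for statistics (percentages get one).
#' @return invisibly, a list with every stage's result and the manifest.
#' @export
run_all <- function(m, geo = NULL, out_dir = "dompopgen_report",
                    model = "band_state",
                    n_perm_amova = 10100, n_perm_mantel = 10000,
                    K_range = 1:10, n_runs = 10, burn_in = 1000, reps = 100000,
                    pcoa_dialect = "gower_raw", seed = 1, digits = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  stage_seeds <- c(amova = seed + 1, pairwise = seed + 2,
                   mantel = seed + 3, admixture = seed + 1000)

  primer <- primer_table(m)
  write_tsv(round_df(primer, digits), pth("primer_table.tsv"))

  divers <- diversity_table(m, model)
  write_tsv(round_df(divers, digits), pth("diversity_table.tsv"))

  d <- squared_distances(m)
  am <- amova(d, m$pops, n_perm = n_perm_amova, seed = stage_seeds[["amova"]])
  am_tab <- data.frame(source = c("Among Pops", "Within Pops", "Total"),
                       df = am$df,
                       SS = round(c(am$SS[c("among", "within", "total")]), digits),
                       Est.Var = round(c(am$sigma2, sum(am$sigma2)), digits),
                       pct = round(c(am$pct, 100), 1),
                       Phi_ST = c(NA, NA, round(am$phi_st, digits)),
                       P = c(NA, NA, signif(am$p_value, 3)))
  write_tsv(am_tab, pth("amova_table.tsv"))

  pw <- pairwise_fst(m, n_perm = 0, seed = stage_seeds[["pairwise"]])
  ds <- nei_distance_matrix(m, model)
  write_tsv(round(pw$fst, digits), pth("pairwise_fst.tsv"), rn = TRUE)
  write_tsv(round(ds, digits), pth("nei_distance.tsv"), rn = TRUE)
  write_tsv(round(combined_triangle(ds, pw$fst), digits),
            pth("distance_fst_combined.tsv"), rn = TRUE)

  part <- diversity_partition(m, model)
  part$NM <- gene_flow(am$phi_st)
  part$Phi_ST <- am$phi_st
  write_tsv(round_df(part, digits), pth("differentiation.tsv"))

  ord <- pcoa(pw$fst, dialect = pcoa_dialect)
  write_tsv(round(cbind(ord$coordinates, percent = NA), digits),
            pth("pcoa_coordinates.tsv"), rn = TRUE)
  write_tsv(data.frame(axis = seq_along(ord$percent),
                       percent = round(ord$percent, 2)),
            pth("pcoa_percent.tsv"))

  mant <- NULL
  if (!is.null(geo)) {
    gkm <- geographic_distance(geo, m$pops)
    mant <- mantel(slatkin_linearized(pw$fst), gkm,
                   n_perm = n_perm_mantel, seed = stage_seeds[["mantel"]])
    write_tsv(data.frame(r = round(mant$r, digits), r2 = round(mant$r2, digits),
                         p = signif(mant$p, 3), n_perm = mant$n_perm),
              pth("mantel.tsv"))
  }

  lnp <- admixture_runs(m, K_range = K_range, n_runs = n_runs,
                        burn_in = burn_in, reps = reps,
                        seed = stage_seeds[["admixture"]])
  write_tsv(round(lnp, 2), pth("lnp_runs.tsv"), rn = TRUE)
  ev <- evanno(lnp)
  write_tsv(round_df(ev, digits), pth("evanno.tsv"))
  best_K <- attr(ev, "optimal_K")
  fit <- fit_admixture(m, best_K, burn_in = burn_in, reps = reps,
                       seed = stage_seeds[["admixture"]])
  write_tsv(round(fit$Q, digits), pth("q_matrix.tsv"), rn = TRUE)
  write_tsv(round(pop_membership(fit, m$pops), digits),
            pth("pop_membership.tsv"), rn = TRUE)

  manifest <- list(
    package = "dompopgen",
    version = as.character(utils::packageVersion("dompopgen")),
    n_samples = n_samples(m), n_loci = n_loci(m),
    populations = as.list(table(m$pops)[unique(m$pops)]),
    model = model, pcoa_dialect = pcoa_dialect,
    seed = seed, stage_seeds = as.list(stage_seeds),
    n_perm_amova = n_perm_amova, n_perm_mantel = n_perm_mantel,
    K_range = K_range, n_runs = n_runs, burn_in = burn_in, reps = reps,
    optimal_K = best_K,
    files = c(list.files(out_dir), "manifest.json")
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(primer = primer, diversity = divers, amova = am,
                 pairwise_fst = pw, nei = ds, partition = part, pcoa = ord,
                 mantel = mant, lnp = lnp, evanno = ev, fit = fit,
                 manifest = manifest))
}
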