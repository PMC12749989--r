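## Structural benchmarks against deposited models ------------------------

#' Structural benchmarks on deposited coordinate files
#'
#' Recomputes the structural quantities used to validate the pipeline
#' against experimentally deposited models, when the user supplies the
#' coordinate files (they are not bundled; download them from the PDB):
#'
#' * pairwise all-atom chain RMSD within a (pseudo-)symmetric trimer
#'   (e.g. the three protomers of the OqxB nanodisc model), reported per
#'   chain pair;
#' * per-protomer porter-domain exit-channel bottleneck radius under the
#'   default channel settings (the widest-path estimator is a deliberate
#'   simplification of Voronoi channel finders, so quantitative agreement
#'   with published channel radii is a validation experiment, not a
#'   guarantee);
#' * C-alpha RMSD of a query protomer onto a reference protomer (e.g. a
#'   variant T protomer onto the wildtype T state), under the C-alpha
#'   policy.
#'
#' @param trimer_path Coordinate file of the trimer to check internally
#'   (chain RMSDs + bottlenecks); `NULL` to skip.
#' @param query_path,reference_path Coordinate files for the protomer
#'   superposition check; `NULL` to skip.
#' @param query_chain,reference_chain Chain ids for the protomer check
#'   (the state-to-chain mapping of deposited models is not standardised
#'   and must be supplied by the user).
#' @param scheme Subdomain scheme matching the trimer's numbering (for the
#'   exit-channel seed residues).
#' @param config A [run_config()].
#' @return Tibble with `metric`, `detail`, `value` rows.
#' @export
structural_benchmarks <- function(trimer_path = NULL,
                                  query_path = NULL, reference_path = NULL,
                                  query_chain = "A", reference_chain = "B",
                                  scheme = default_scheme("oqxb"),
                                  config = run_config()) {
  rows <- list()
  if (!is.null(trimer_path)) {
    trimer <- read_structure(trimer_path)
    chains <- unique(trimer$chain)[1:3]
    for (i in 1:2) for (j in (i + 1):3) {
      fit <- kabsch_superpose(trimer[trimer$chain == chains[i], ],
                              trimer[trimer$chain == chains[j], ],
                              selection = "all",
                              chain_map = setNames(chains[j], chains[i]))
      rows <- c(rows, list(tibble(
        metric = "chain_rmsd_all_atom",
        detail = paste0(chains[i], "-", chains[j]), value = fit$rmsd)))
    }
    for (ch in chains) {
      mono <- as_structure(trimer[trimer$chain == ch, ],
                           model_id = paste0("protomer_", ch))
      det <- detect_O_star(mono, scheme, config)
      rows <- c(rows, list(tibble(
        metric = "exit_bottleneck_radius", detail = ch,
        value = det$bottleneck)))
    }
  }
  if (!is.null(query_path) && !is.null(reference_path)) {
    q <- read_structure(query_path)
    r <- read_structure(reference_path)
    fit <- kabsch_superpose(q[q$chain == query_chain, ],
                            r[r$chain == reference_chain, ],
                            selection = "calpha",
                            chain_map = setNames(reference_chain, query_chain))
    rows <- c(rows, list(tibble(
      metric = "protomer_ca_rmsd",
      detail = paste0(query_chain, "->", reference_chain), value = fit$rmsd)))
  }
  if (!length(rows))
    abort("no benchmark inputs supplied", class = "rnd_config_error")
  purrr::list_rbind(rows)
}
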