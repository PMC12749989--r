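## Trimer composition census ---------------------------------------------
##
## Reconstructs trimer compositions from per-monomer labels and computes
## monomer- and trimer-level frequency distributions. Compositions are
## unordered multisets of three states with canonical names in precedence
## order L < T < O < O* ("TTO", never "OTT"); aliases are accepted on
## input. Monomer frequencies are derived from the composition counts, so
## the identity f_s = sum_c p(c) n_s(c) / 3 holds structurally.

## split a composition name into state tokens ("O*" before "O")
comp_tokens <- function(name) {
  m <- gregexpr("O\\*|O|T|L", name)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(name))
    abort(paste0("cannot parse composition name: ", name),
          class = "rnd_census_error")
  substring(name, m, m + attr(m, "match.length") - 1)
}

#' Canonical trimer composition name
#'
#' Sorts three state labels by the fixed precedence L < T < O < O* and
#' concatenates them, so `{T, O, T}`, `"OTT"` and `"TTO"` all canonicalise
#' to `"TTO"`. The name is invariant under any permutation of the monomers.
#'
#' @param labels Character vector of three state labels, or a composition
#'   name (alias) to canonicalise.
#' @return The canonical composition name.
#' @export
canonical_composition <- function(labels) {
  if (length(labels) == 1 && nchar(labels) > 2) labels <- comp_tokens(labels)
  if (length(labels) != 3)
    abort("a trimer composition has exactly 3 states", class = "rnd_census_error")
  bad <- setdiff(labels, STATES)
  if (length(bad))
    abort(paste0("unknown state(s) in composition: ", paste(bad, collapse = ", ")),
          class = "rnd_census_error")
  paste(labels[order(match(labels, STATES))], collapse = "")
}

## per-composition state-count matrix: rows = compositions, cols = STATES
comp_state_counts <- function(comps) {
  out <- matrix(0L, length(comps), length(STATES),
                dimnames = list(comps, STATES))
  for (i in seq_along(comps)) {
    tk <- comp_tokens(comps[i])
    for (s in tk) out[i, s] <- out[i, s] + 1L
  }
  out
}

#' Aggregate per-monomer labels into a state census
#'
#' Particles with exactly three assigned (non-`UNASSIGNED`) monomers form
#' trimer compositions; all other particles are dropped and reported, not
#' imputed. Monomer frequencies are computed from the composition counts
#' (composition-weighted state counts divided by 3), so monomer and trimer
#' panels are consistent by construction.
#'
#' @param labels A label table (see [validate_labels()]).
#' @return A list of class `state_census`: `n_particles_complete`,
#'   `n_particles_dropped`, `monomer_counts`, `monomer_freqs` (over L, T,
#'   O, O*), `trimer_counts`, `trimer_freqs`, `compositions` (per-particle
#'   tibble), `ci` (`NULL` until [bootstrap_census()]).
#' @export
aggregate_census <- function(labels) {
  labels <- validate_labels(labels)
  if (!nrow(labels)) abort("empty label table", class = "rnd_census_error")
  ## vectorised composition construction: copy_index uniqueness caps a
  ## particle at 3 rows, so complete = exactly 3 rows, none UNASSIGNED
  pid <- factor(labels$particle_id)
  n_rows <- tabulate(pid, nbins = nlevels(pid))
  n_unassigned <- as.integer(rowsum((labels$state_label == UNASSIGNED) + 0L,
                                    pid)[, 1])
  complete_lvl <- n_rows == 3L & n_unassigned == 0L
  n_complete <- sum(complete_lvl)
  n_dropped <- nlevels(pid) - n_complete
  if (!n_complete)
    abort("no complete particles (3 assigned monomers)", class = "rnd_empty_census")
  keep <- complete_lvl[as.integer(pid)]
  ord <- order(as.integer(pid)[keep], state_rank(labels$state_label[keep]))
  lab_sorted <- matrix(labels$state_label[keep][ord], nrow = 3)
  comp_vec <- paste0(lab_sorted[1, ], lab_sorted[2, ], lab_sorted[3, ])
  complete <- tibble(particle_id = levels(pid)[complete_lvl], comp = comp_vec)
  tc <- table(complete$comp)
  trimer_counts <- setNames(as.integer(tc), names(tc))
  ## canonical ordering of composition names: by state ranks
  ord <- order(vapply(names(trimer_counts), function(nm)
    paste(sprintf("%02d", match(comp_tokens(nm), STATES)), collapse = ""),
    character(1)))
  trimer_counts <- trimer_counts[ord]
  trimer_freqs <- trimer_counts / n_complete
  M <- comp_state_counts(names(trimer_counts))
  monomer_counts <- setNames(as.integer(t(M) %*% trimer_counts), STATES)
  monomer_freqs <- monomer_counts / (3 * n_complete)
  structure(list(n_particles_complete = n_complete,
                 n_particles_dropped = n_dropped,
                 monomer_counts = monomer_counts,
                 monomer_freqs = monomer_freqs,
                 trimer_counts = trimer_counts,
                 trimer_freqs = trimer_freqs,
                 compositions = complete[, c("particle_id", "comp")],
                 ci = NULL),
            class = "state_census")
}

#' @export
print.state_census <- function(x, ...) {
  cat(sprintf("# state census: %d complete particles (%d dropped)\n",
              x$n_particles_complete, x$n_particles_dropped))
  mf <- x$monomer_freqs[x$monomer_freqs > 0 | names(x$monomer_freqs) %in%
                          names(x$monomer_counts)[x$monomer_counts > 0]]
  cat("# monomer %:", paste(sprintf("%s %.1f", names(x$monomer_freqs),
                                    100 * x$monomer_freqs), collapse = ", "), "\n")
  cat("# trimer  %:", paste(sprintf("%s %.1f", names(x$trimer_freqs),
                                    100 * x$trimer_freqs), collapse = ", "), "\n")
  invisible(x)
}

#' Monomer frequencies implied by a composition distribution
#'
#' The composition-weighted identity `f_s = sum_c p(c) n_s(c) / 3` linking
#' the trimer-level distribution to the monomer-level one. Composition-name
#' aliases are accepted and merged. If the input does not sum to 1 within
#' `1e-6` the call errors rather than silently renormalising.
#'
#' @param trimer_freqs Named numeric vector (or one-column data frame) of
#'   composition frequencies.
#' @return Named numeric vector of monomer frequencies over L, T, O, O*
#'   (sums to 1).
#' @export
implied_monomer_frequencies <- function(trimer_freqs) {
  p <- unlist(trimer_freqs)
  if (is.null(names(p)) || any(!nzchar(names(p))))
    abort("composition frequencies must be named", class = "rnd_census_error")
  if (any(p < 0)) abort("negative composition frequency", class = "rnd_census_error")
  nm <- vapply(names(p), canonical_composition, character(1))
  p <- tapply(p, nm, sum)
  if (abs(sum(p) - 1) > 1e-6)
    abort(sprintf("composition frequencies sum to %.6f, not 1; renormalize deliberately before calling",
                  sum(p)), class = "rnd_census_error")
  M <- comp_state_counts(names(p))
  f <- as.numeric(t(M) %*% as.numeric(p)) / 3
  setNames(f / sum(f), STATES)
}

#' Particle-level bootstrap intervals for a census
#'
#' Nonparametric bootstrap resampling whole particles (keeping the three
#' labels of a particle together, preserving intra-trimer correlation);
#' percentile 95% intervals for every monomer and trimer frequency.
#' Reproducible under a fixed seed.
#'
#' @param labels A label table.
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return The `state_census` with `ci` filled: a list of two tibbles
#'   (`monomer`, `trimer`) with `lo`/`hi` columns.
#' @export
bootstrap_census <- function(labels, B = 200L, seed = 1L, conf = 0.95) {
  if (B < 1) abort("B must be >= 1", class = "rnd_census_error")
  census <- aggregate_census(labels)
  comps <- census$compositions$comp
  lev <- names(census$trimer_counts)
  M <- comp_state_counts(lev)
  n <- length(comps)
  ci <- comps_boot(comps, lev, M, n, B, seed, conf)
  census$ci <- ci
  census
}

## bootstrap engine on the per-particle composition vector
comps_boot <- function(comps, lev, M, n, B, seed, conf) {
  set.seed(seed)
  f <- factor(comps, levels = lev)
  tf <- matrix(NA_real_, B, length(lev), dimnames = list(NULL, lev))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tf[b, ] <- tabulate(f[idx], nbins = length(lev)) / n
  }
  mf <- tf %*% M / 3
  a <- (1 - conf) / 2
  qs <- function(m) apply(m, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  qt <- qs(tf); qm <- qs(mf)
  list(monomer = tibble(state = colnames(mf), lo = qm[1, ], hi = qm[2, ]),
       trimer = tibble(composition = lev, lo = qt[1, ], hi = qt[2, ]))
}

#' G-test of monomer-state independence
#'
#' Tests whether the observed trimer compositions are consistent with the
#' three monomer states being drawn independently from the observed
#' monomer frequencies. Expected composition probabilities are multinomial:
#' `P(c) = 3! / prod_s n_s(c)! * prod_s f_s^{n_s(c)}`. Categories with
#' expected count below 1 are pooled; degrees of freedom are the number of
#' (pooled) composition categories with nonzero expectation minus the
#' number of states with nonzero frequency.
#'
#' @param census A `state_census`.
#' @return A list of class `census_gtest`: `g_statistic`, `dof`, `p_value`,
#'   and a `table` tibble of observed/expected counts.
#' @export
independence_test <- function(census) {
  n <- census$n_particles_complete
  f <- census$monomer_freqs[census$monomer_freqs > 0]
  states <- names(f)
  ## all multisets of size 3 from the observed states
  grid <- expand.grid(rep(list(states), 3), stringsAsFactors = FALSE)
  comps <- unique(apply(grid, 1, function(r) canonical_composition(r)))
  M <- comp_state_counts(comps)[, states, drop = FALSE]
  pc <- vapply(seq_along(comps), function(i) {
    ns <- M[i, ]
    factorial(3) / prod(factorial(ns)) * prod(f^ns)
  }, numeric(1))
  obs <- setNames(rep(0L, length(comps)), comps)
  got <- census$trimer_counts
  obs[names(got)] <- got
  exp_counts <- n * pc
  if (length(states) == 1 || length(comps) == 1)
    return(structure(list(g_statistic = 0, dof = 0L, p_value = 1,
                          table = tibble(composition = comps, observed = as.integer(obs),
                                         expected = exp_counts)),
                     class = "census_gtest"))
  ## pool categories with expected count < 1
  pool <- exp_counts < 1
  tab <- tibble(composition = comps, observed = as.integer(obs),
                expected = exp_counts)
  if (any(pool) && sum(pool) > 1) {
    kept <- tab[!pool, , drop = FALSE]
    pooled <- tibble(composition = "pooled",
                     observed = sum(tab$observed[pool]),
                     expected = sum(tab$expected[pool]))
    tab2 <- dplyr::bind_rows(kept, pooled)
  } else tab2 <- tab
  o <- tab2$observed; e <- tab2$expected
  keep <- e > 0
  g <- 2 * sum(ifelse(o[keep] > 0, o[keep] * log(o[keep] / e[keep]), 0))
  dof <- sum(keep) - length(states)
  p <- if (dof < 1) 1 else pchisq(g, dof, lower.tail = FALSE)
  structure(list(g_statistic = g, dof = as.integer(max(dof, 0)), p_value = p,
                 table = tab),
            class = "census_gtest")
}

#' @export
print.census_gtest <- function(x, ...) {
  cat(sprintf("# G-test of monomer independence: G = %.3f, df = %d, p = %.3g\n",
              x$g_statistic, x$dof, x$p_value))
  invisible(x)
}

#' Census summary as JSON
#'
#' Full-precision frequencies for machine use (printed tables round to one
#' decimal percentage).
#'
#' @param census A `state_census`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_census_json <- function(census, path) {
  x <- list(n_particles_complete = census$n_particles_complete,
            n_particles_dropped = census$n_particles_dropped,
            monomer_counts = as.list(census$monomer_counts),
            monomer_freqs = as.list(census$monomer_freqs),
            trimer_counts = as.list(census$trimer_counts),
            trimer_freqs = as.list(census$trimer_freqs))
  if (!is.null(census$ci)) x$ci <- list(
    monomer = census$ci$monomer, trimer = census$ci$trimer)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
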