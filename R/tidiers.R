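## broom-style tidiers ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a state census
#'
#' @param x A `state_census`.
#' @param level `"monomer"` or `"trimer"`.
#' @param ... Unused.
#' @return A tibble with one row per state (or composition): counts,
#'   frequencies and, after [bootstrap_census()], `conf.low`/`conf.high`.
#' @method tidy state_census
#' @export
tidy.state_census <- function(x, level = c("monomer", "trimer"), ...) {
  level <- match.arg(level)
  if (level == "monomer") {
    out <- tibble(state = names(x$monomer_freqs),
                  count = as.integer(x$monomer_counts),
                  freq = as.numeric(x$monomer_freqs))
    if (!is.null(x$ci))
      out <- dplyr::left_join(out,
                              dplyr::rename(x$ci$monomer, conf.low = "lo",
                                            conf.high = "hi"),
                              by = "state")
  } else {
    out <- tibble(composition = names(x$trimer_freqs),
                  count = as.integer(x$trimer_counts),
                  freq = as.numeric(x$trimer_freqs))
    if (!is.null(x$ci))
      out <- dplyr::left_join(out,
                              dplyr::rename(x$ci$trimer, conf.low = "lo",
                                            conf.high = "hi"),
                              by = "composition")
  }
  out
}

#' Census summary row
#'
#' @param x A `state_census`.
#' @param ... Unused.
#' @return One-row tibble: particle counts and category counts.
#' @method glance state_census
#' @export
glance.state_census <- function(x, ...) {
  tibble(n_particles_complete = x$n_particles_complete,
         n_particles_dropped = x$n_particles_dropped,
         n_states = sum(x$monomer_counts > 0),
         n_compositions = length(x$trimer_counts))
}

#' Tidy a monomer-independence G-test
#'
#' @param x A `census_gtest`.
#' @param ... Unused.
#' @return Observed/expected counts per composition category.
#' @method tidy census_gtest
#' @export
tidy.census_gtest <- function(x, ...) x$table

#' One-row G-test summary
#'
#' @param x A `census_gtest`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @method glance census_gtest
#' @export
glance.census_gtest <- function(x, ...)
  tibble(statistic = x$g_statistic, df = x$dof, p.value = x$p_value)

#' Tidy a Kabsch fit
#'
#' @param x A `kabsch_fit`.
#' @param ... Unused.
#' @return One-row tibble: `rmsd`, `n_atoms`, `rotation_angle`
#'   (degrees) and translation components.
#' @method glance kabsch_fit
#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         rotation_angle = rotation_angle(x$transform$R),
         tx = x$transform$t[1], ty = x$transform$t[2], tz = x$transform$t[3],
         selection = x$selection)
}

#' Tidy a channel result
#'
#' @param x A `channel_result`.
#' @param ... Unused.
#' @return The along-channel profile (see [channel_profile()]).
#' @method tidy channel_result
#' @export
tidy.channel_result <- function(x, ...) channel_profile(x)

#' One-row channel summary
#'
#' @param x A `channel_result`.
#' @param ... Unused.
#' @return Tibble with `bottleneck_radius`, `n_nodes`, `path_length`,
#'   `reached_exterior`.
#' @method glance channel_result
#' @export
glance.channel_result <- function(x, ...) {
  prof <- channel_profile(x)
  tibble(bottleneck_radius = x$bottleneck_radius,
         n_nodes = nrow(x$path),
         path_length = max(prof$arc_length),
         reached_exterior = x$reached_exterior)
}
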