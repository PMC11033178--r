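# Lick microstructure (clusters of licks, licks per cluster) and fluid
# intake dosing for two-bottle choice sessions.

#' Lick clusters
#'
#' Segments a lick train into clusters (drinking bouts for microstructure
#' purposes): maximal runs of licks whose gaps are strictly below
#' `split_ili`. The cluster criterion for microstructure is conventionally
#' longer than the 210 ms cycle criterion; 0.5 s is the default here.
#' Cluster count indexes motivation to initiate drinking; mean licks per
#' cluster indexes palatability.
#'
#' @param lick_times Ascending lick times, seconds.
#' @param split_ili Cluster-splitting inter-lick interval, seconds (> 0).
#' @return A list of class `lick_clusters`: `n_clusters`,
#'   `licks_per_cluster` (mean), `total_licks`, `split_ili`, and `clusters`
#'   (tibble `cluster`, `start_s`, `end_s`, `n_licks`).
#' @export
lick_clusters <- function(lick_times, split_ili = 0.5) {
  stopifnot(is.numeric(lick_times), split_ili > 0)
  if (is.unsorted(lick_times)) stop("`lick_times` must be ascending",
                                    call. = FALSE)
  if (length(lick_times) == 0) {
    cl <- tibble::tibble(cluster = integer(), start_s = numeric(),
                         end_s = numeric(), n_licks = integer())
    return(structure(list(n_clusters = 0L, licks_per_cluster = NaN,
                          total_licks = 0L, split_ili = split_ili,
                          clusters = cl),
                     class = "lick_clusters"))
  }
  id <- cumsum(c(1L, as.integer(diff(lick_times) >= split_ili)))
  cl <- tibble::tibble(time_s = lick_times, cluster = id) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(start_s = min(.data$time_s), end_s = max(.data$time_s),
                     n_licks = dplyr::n(), .groups = "drop")
  structure(list(
    n_clusters = nrow(cl),
    licks_per_cluster = mean(cl$n_licks),
    total_licks = length(lick_times),
    split_ili = split_ili,
    clusters = cl), class = "lick_clusters")
}

#' @export
print.lick_clusters <- function(x, ...) {
  cat("<lick_clusters> ", x$n_clusters, " clusters, ",
      x$total_licks, " licks (",
      format(x$licks_per_cluster, digits = 4), " per cluster), split at ",
      x$split_ili, " s\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lick_clusters <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.lick_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 licks_per_cluster = x$licks_per_cluster,
                 total_licks = x$total_licks,
                 split_ili = x$split_ili)
}

#' Intake dose from bottle weights
#'
#' Converts pre/post bottle weights to the consumed dose in grams of solute
#' (or ethanol) per kilogram body weight. For `basis = "v/v"` solutions
#' (ethanol), consumed mass is converted to volume with `density_solution`
#' (default 1.0 g/mL) and dosed as
#' `volume * concentration * density_ethanol / body_weight`; for
#' `basis = "w/v"` solutes (sucrose), `volume * concentration / body_weight`
#' (concentration in g/mL, i.e. 14.2% w/v = 0.142). A negative weight change
#' (spillage or condensation) is flagged with a warning and clamped to zero.
#'
#' @param bottle_pre_g,bottle_post_g Bottle weights before/after, grams.
#' @param solution Solution identity label (e.g. `"ethanol"`, `"sucrose"`).
#' @param concentration Concentration as a fraction (0.10 for 10%).
#' @param basis `"v/v"` or `"w/v"`.
#' @param body_weight_kg Body weight, kg (> 0).
#' @param spout Spout id copied into the record.
#' @param density_solution Solution density, g/mL.
#' @param density_ethanol Ethanol density, g/mL (0.789).
#' @return A one-row tibble: `spout`, `solution`, `concentration`, `basis`,
#'   `consumed_g`, `dose_g_per_kg`.
#' @examples
#' # 10 g of 10% v/v ethanol drunk by a 0.4 kg rat: 1.9725 g/kg
#' intake_dose(100, 90, "ethanol", 0.10, "v/v", 0.4)
#' @export
intake_dose <- function(bottle_pre_g, bottle_post_g, solution, concentration,
                        basis = c("v/v", "w/v"), body_weight_kg,
                        spout = "a", density_solution = 1.0,
                        density_ethanol = 0.789) {
  basis <- match.arg(basis)
  stopifnot(body_weight_kg > 0, concentration >= 0, density_solution > 0)
  delta <- bottle_pre_g - bottle_post_g
  if (delta < 0) {
    warning("bottle gained weight (", format(-delta),
            " g); consumed mass clamped to 0", call. = FALSE)
    delta <- 0
  }
  volume_ml <- delta / density_solution
  dose <- switch(basis,
                 "v/v" = volume_ml * concentration * density_ethanol,
                 "w/v" = volume_ml * concentration) / body_weight_kg
  tibble::tibble(spout = spout, solution = solution,
                 concentration = concentration, basis = basis,
                 consumed_g = delta, dose_g_per_kg = dose)
}

#' Per-spout microstructure summary of a session
#'
#' For each spout: lick-cluster counts and sizes at `split_ili`, the intake
#' dose from the session's bottle weights and solution descriptors, and —
#' when the session uses a closed-loop laser — the stimulation-trigger count
#' recomputed from the lick train via [simulate_closed_loop()], checked for
#' consistency against the recorded `laser_on` events.
#'
#' @param session A `lick_session`.
#' @param split_ili Cluster criterion, seconds.
#' @return A tibble with one row per spout: `spout`, `n_clusters`,
#'   `licks_per_cluster`, `total_licks`, `consumed_g`, `dose_g_per_kg`,
#'   `laser_triggers` (NA when no laser on that spout), `split_ili`.
#' @export
session_microstructure <- function(session, split_ili = 0.5) {
  validate_session(session)
  md <- session$metadata
  spouts <- md$solutions$spout
  licks <- session$events |> dplyr::filter(.data$event_type == "lick")
  recorded_on <- sum(session$events$event_type == "laser_on")
  rows <- purrr::map_dfr(spouts, function(sp) {
    lt <- sort(licks$time_s[licks$spout == sp])
    cl <- lick_clusters(lt, split_ili)
    sol <- md$solutions[md$solutions$spout == sp, ]
    bw <- md$bottle_weights[md$bottle_weights$spout == sp, ]
    dose <- intake_dose(bw$pre_g, bw$post_g, sol$solution,
                        sol$concentration, sol$basis, md$body_weight_kg,
                        spout = sp)
    trig <- NA_integer_
    if (!is.null(md$laser_mode) && md$laser_mode != "none" &&
        identical(md$laser_spout, sp)) {
      lz <- simulate_closed_loop(lt, md$laser_mode)
      trig <- nrow(lz)
      if (recorded_on > 0 && trig != recorded_on) {
        warning("recomputed laser triggers (", trig,
                ") differ from recorded laser_on events (", recorded_on, ")",
                call. = FALSE)
      }
    }
    tibble::tibble(spout = sp,
                   n_clusters = cl$n_clusters,
                   licks_per_cluster = ifelse(cl$total_licks > 0,
                                              cl$licks_per_cluster, 0),
                   total_licks = cl$total_licks,
                   consumed_g = dose$consumed_g,
                   dose_g_per_kg = dose$dose_g_per_kg,
                   laser_triggers = trig)
  })
  dplyr::mutate(rows, split_ili = split_ili)
}
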