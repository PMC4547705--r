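#' Observed generation-resolved cell counts
#'
#' Long-format per-animal, per-organ, per-generation counts from a
#' sacrifice design: every animal is measured at exactly one time step
#' (measurements at different steps come from different individuals).
#' Organs are the measured compartments only (source and sinks; transfer
#' stages cannot be assayed).
#'
#' @param df data.frame with columns `animal_id`, `time_hours`, `n`,
#'   `organ`, `generation`, `count`.
#' @param topology an `mgw_topology` fixing the admissible organ labels.
#' @param p maximum generation.
#' @param dt_hours,t0_hours time convention used to cross-check
#'   `time_hours == t0_hours + dt_hours * n`.
#' @return the data.frame with class `mgw_dataset`.
#' @export
observed_dataset <- function(df, topology = network_topology(), p = 7,
                             dt_hours = 4, t0_hours = 72) {
  need <- c("animal_id", "time_hours", "n", "organ", "generation", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  organs <- c(topology$source, topology$sinks)
  bad <- which(!(df$organ %in% organs))
  if (length(bad)) stop("unknown organ label '", df$organ[bad[1]],
                        "' in row ", bad[1])
  bad <- which(df$count < 0 | df$count != round(df$count) | !is.finite(df$count))
  if (length(bad)) stop("count must be a non-negative integer in row ", bad[1],
                        " (value ", df$count[bad[1]], ")")
  bad <- which(df$generation < 0 | df$generation > p)
  if (length(bad)) stop("generation out of 0..", p, " in row ", bad[1])
  bad <- which(abs(df$time_hours - (t0_hours + dt_hours * df$n)) > 1e-8)
  if (length(bad)) stop("time_hours does not equal ", t0_hours, " + ",
                        dt_hours, " * n in row ", bad[1])
  steps_per_animal <- tapply(df$n, df$animal_id, function(x) length(unique(x)))
  if (any(steps_per_animal > 1))
    stop("animal(s) measured at more than one time step: ",
         paste(names(steps_per_animal)[steps_per_animal > 1], collapse = ", "),
         " (sacrificed animals appear at exactly one step)")
  df$count <- as.numeric(df$count)
  df$n <- as.integer(df$n)
  df$time_hours <- as.numeric(df$time_hours)
  df$generation <- as.integer(df$generation)
  rownames(df) <- NULL
  class(df) <- c("mgw_dataset", "data.frame")
  attr(df, "p") <- as.integer(p)
  attr(df, "dt_hours") <- dt_hours
  attr(df, "t0_hours") <- t0_hours
  df
}

#' Per-animal relative frequencies
#'
#' Normalizes each animal's counts by its total over the given organ
#' scope (all measured organs jointly by default, mirroring the
#' likelihood's normalizing variable).
#'
#' @param data an `mgw_dataset`.
#' @param scope `"global"` (one frequency vector per animal across all
#'   measured organs) or `"per_organ"`.
#' @return data.frame of the dataset rows with a `frequency` column
#'   (NA for animals/scopes with zero total).
#' @export
animal_frequencies <- function(data, scope = c("global", "per_organ")) {
  scope <- match.arg(scope)
  key <- if (scope == "global") data$animal_id
         else paste(data$animal_id, data$organ, sep = "\r")
  tot <- stats::ave(data$count, key, FUN = sum)
  out <- as.data.frame(data)
  out$frequency <- ifelse(tot > 0, data$count / tot, NA_real_)
  out
}

#' Initial source population from the step-0 animals
#'
#' The likelihood needs the cell counts in the draining node at the first
#' time point; this takes the mean over the animals sacrificed at step 0
#' of their source-organ generation counts, treated as a deterministic
#' initial state (zero covariance).
#'
#' @param data an `mgw_dataset`.
#' @param params an `mgw_parameters` (for `p`).
#' @param topology an `mgw_topology`.
#' @return numeric count vector over the type space.
#' @export
initial_state_from_data <- function(data, params, topology = network_topology()) {
  ts <- build_type_space(topology, params$p)
  d0 <- data[data$n == 0L & data$organ == topology$source, , drop = FALSE]
  if (!nrow(d0)) stop("no step-0 source-organ records to build the initial state")
  n_animals <- length(unique(d0$animal_id))
  z0 <- numeric(nrow(ts))
  agg <- tapply(d0$count, d0$generation, sum)
  gens <- as.integer(names(agg))
  z0[type_index(ts, topology$source, gens)] <- as.numeric(agg) / n_animals
  z0
}
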