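## Behavioral usage, habituation curves, spatial occupancy and
## grooming-mode decomposition from ethograms.

#' Normalized behavioral usage
#'
#' Fraction of frames spent in each behavioral label over a trial; the rows
#' of all usage tables sum to one.
#'
#' @param eth ethogram tibble (see [make_ethogram()]).
#' @param level `"coarse"` or `"fine"`.
#' @param vocabulary labels defining the columns (zero-usage labels kept);
#'   defaults to [of_states()] for coarse, observed range for fine.
#' @return one-row tibble of fractions, one column per label.
#' @export
usage <- function(eth, level = c("coarse", "fine"), vocabulary = NULL) {
  level <- match.arg(level)
  labels <- eth[[level]]
  if (length(labels) == 0) stop("empty ethogram", call. = FALSE)
  if (is.null(vocabulary)) {
    vocabulary <- if (level == "coarse") of_states() else seq_len(max(labels))
  }
  cnt <- table(factor(labels, levels = vocabulary))
  tibble::as_tibble(as.list(as.numeric(cnt) / length(labels)),
                    .name_repair = ~ as.character(vocabulary))
}

#' Usage tables for a cohort
#'
#' @param eths named list of ethograms (one per mouse/trial), or a tibble
#'   with a `mouse` column plus ethogram columns.
#' @param level `"coarse"` or `"fine"`.
#' @param vocabulary see [usage()].
#' @return tibble: one row per mouse, `mouse` column plus one fraction
#'   column per label.
#' @export
usage_table <- function(eths, level = "coarse", vocabulary = NULL) {
  if (is.data.frame(eths)) eths <- split(eths, eths$mouse)
  if (is.null(names(eths))) names(eths) <- paste0("m", seq_along(eths))
  rows <- lapply(names(eths), function(nm) {
    dplyr::bind_cols(tibble::tibble(mouse = nm),
                     usage(eths[[nm]], level, vocabulary))
  })
  dplyr::bind_rows(rows)
}

#' Sliding-window usage over time with group confidence bands
#'
#' Per-class usage in sliding windows for each mouse, with the group mean
#' and a percentile-bootstrap confidence interval across mice per window.
#'
#' @param eths named list of ethograms (>= 2 for a CI), or a tibble with a
#'   `mouse` column.
#' @param frame_rate Hz.
#' @param window_s window length, s (default 180).
#' @param step_s window step, s (default 30).
#' @param level `"coarse"` or `"fine"`.
#' @param n_boot bootstrap resamples over mice (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return tibble: `window_mid_s`, `class`, `mean`, `lo`, `hi` plus a
#'   `per_mouse` attribute (mouse x window x class usage tibble).
#' @export
usage_over_time <- function(eths, frame_rate, window_s = 180, step_s = 30,
                            level = "coarse", n_boot = 1000, conf = 0.95,
                            seed = 1) {
  if (is.data.frame(eths)) eths <- split(eths, eths$mouse)
  if (is.null(names(eths))) names(eths) <- paste0("m", seq_along(eths))
  n_frames <- min(vapply(eths, nrow, integer(1)))
  win <- round(window_s * frame_rate)
  if (win > n_frames) stop("window longer than the trial", call. = FALSE)
  step <- max(1L, round(step_s * frame_rate))
  starts <- seq(1L, n_frames - win + 1L, by = step)
  vocab <- if (level == "coarse") of_states() else
    seq_len(max(unlist(lapply(eths, function(e) max(e$fine)))))
  per_mouse <- dplyr::bind_rows(lapply(names(eths), function(nm) {
    lab <- eths[[nm]][[level]]
    dplyr::bind_rows(lapply(starts, function(s) {
      u <- table(factor(lab[s:(s + win - 1L)], levels = vocab)) / win
      tibble::tibble(mouse = nm, window_mid_s = (s - 1 + win / 2) / frame_rate,
                     class = as.character(vocab), usage = as.numeric(u))
    }))
  }))
  nm <- length(eths)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  alpha <- (1 - conf) / 2
  boot_ci <- function(u) {
    if (nm < 2) return(c(mean(u), mean(u), mean(u)))
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(u[sample.int(nm, nm, TRUE)]), numeric(1))
    c(mean(u), stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE))
  }
  out <- per_mouse |>
    dplyr::group_by(.data$window_mid_s, .data$class) |>
    dplyr::summarise(ci = list(boot_ci(.data$usage)), .groups = "drop") |>
    dplyr::mutate(mean = vapply(.data$ci, `[`, numeric(1), 1),
                  lo = vapply(.data$ci, `[`, numeric(1), 2),
                  hi = vapply(.data$ci, `[`, numeric(1), 3)) |>
    dplyr::select(-"ci")
  ## guarantee the band contains the mean even at degenerate draws
  out$lo <- pmin(out$lo, out$mean)
  out$hi <- pmax(out$hi, out$mean)
  attr(out, "per_mouse") <- per_mouse
  out
}

#' Arena zone geometry
#'
#' Default geometry: a corner square of side `arena_side/4` in each corner
#' and a concentric center square of side `arena_side/2`.
#'
#' @param arena_side arena side, m.
#' @param corner_side corner-zone square side, m.
#' @param center_side center-zone square side, m.
#' @return object of class `zone_config`.
#' @export
zone_config <- function(arena_side = 0.457, corner_side = arena_side / 4,
                        center_side = arena_side / 2) {
  stopifnot(corner_side > 0, center_side > 0, center_side < arena_side)
  ## corner and center zones must not overlap
  if (corner_side > (arena_side - center_side) / 2) {
    stop("corner and center zones overlap", call. = FALSE)
  }
  structure(list(arena_side = arena_side, corner_side = corner_side,
                 center_side = center_side), class = "zone_config")
}

## zone membership per frame: "corner", "center", "edge", "open"
.zone_membership <- function(x, y, zones) {
  L <- zones$arena_side; cs <- zones$corner_side; ce <- zones$center_side
  in_corner <- (x <= cs | x >= L - cs) & (y <= cs | y >= L - cs)
  lo <- (L - ce) / 2; hi <- (L + ce) / 2
  in_center <- x >= lo & x <= hi & y >= lo & y <= hi
  edge_w <- cs
  in_edge <- !in_corner & !in_center &
    (x <= edge_w | x >= L - edge_w | y <= edge_w | y >= L - edge_w)
  out <- rep("open", length(x))
  out[in_edge] <- "edge"
  out[in_center] <- "center"
  out[in_corner] <- "corner"
  out
}

#' Spatial occupancy, corner time and center crossings
#'
#' Per-class 2-D occupancy maps, the fraction of frames spent in any corner
#' zone, and the number of entries into the center zone. Center crossings
#' are counted on a zone-membership sequence cleaned with a hysteresis of
#' `hysteresis_s` (membership blips shorter than this are absorbed), which
#' suppresses boundary jitter.
#'
#' @param eth ethogram with arena coordinates `x`, `y` (m).
#' @param zones a [zone_config()].
#' @param frame_rate Hz.
#' @param grid_n occupancy map resolution (default 20).
#' @param hysteresis_s hysteresis for crossing detection (default 0.5).
#' @return list: `maps` (named list of `grid_n x grid_n` matrices, one per
#'   class, each summing to 1), `corner_fraction`, `center_crossings`,
#'   `zone_fractions` (tibble over corner/edge/center/open), `n_clipped`.
#' @export
spatial_occupancy <- function(eth, zones = zone_config(), frame_rate,
                              grid_n = 20, hysteresis_s = 0.5) {
  if (anyNA(eth$x) || anyNA(eth$y)) stop("arena coordinates required", call. = FALSE)
  L <- zones$arena_side
  x <- eth$x; y <- eth$y
  n_clipped <- sum(x < 0 | x > L | y < 0 | y > L)
  if (n_clipped > 0) message(sprintf("%d coordinates clipped to the arena", n_clipped))
  x <- pmin(pmax(x, 0), L); y <- pmin(pmax(y, 0), L)
  zm <- .zone_membership(x, y, zones)
  corner_fraction <- mean(zm == "corner")
  zone_fractions <- tibble::tibble(
    zone = c("corner", "edge", "center", "open"),
    fraction = vapply(c("corner", "edge", "center", "open"),
                      function(z) mean(zm == z), numeric(1))
  )
  ## center crossings with hysteresis
  inc <- zm == "center"
  inc <- absorb_short_runs(inc, max(1L, round(hysteresis_s * frame_rate)))
  center_crossings <- sum(diff(inc) == 1)
  ## occupancy maps per class
  brk <- seq(0, L, length.out = grid_n + 1)
  ix <- pmin(findInterval(x, brk, all.inside = TRUE), grid_n)
  iy <- pmin(findInterval(y, brk, all.inside = TRUE), grid_n)
  maps <- lapply(split(seq_along(x), eth$coarse), function(sel) {
    m <- matrix(0, grid_n, grid_n)
    t <- table(factor(ix[sel], levels = 1:grid_n),
               factor(iy[sel], levels = 1:grid_n))
    m[] <- as.numeric(t) / length(sel)
    m
  })
  list(maps = maps, corner_fraction = corner_fraction,
       center_crossings = center_crossings,
       zone_fractions = zone_fractions, n_clipped = n_clipped)
}

#' Grooming-mode decomposition
#'
#' Splits grooming frames into modes via a fine-cluster-to-mode submap,
#' merges blips shorter than the minimum episode duration into the
#' surrounding episode, and counts episodes per mode, raw and normalized
#' over all grooming episodes.
#'
#' @param eth ethogram tibble.
#' @param groom_submap named vector mapping fine cluster id (as character)
#'   to a grooming mode label; must cover all fine clusters whose coarse
#'   class is `groom_class`.
#' @param groom_class coarse label treated as grooming (default "groom").
#' @param min_bout_frames minimum episode length (default 20 frames,
#'   i.e. 250 ms at 80 Hz).
#' @return tibble: `mode`, `episodes`, `frames`, `episode_fraction`,
#'   `frame_fraction`; zero rows if the mouse never grooms (with a message).
#' @export
grooming_modes <- function(eth, groom_submap, groom_class = "groom",
                           min_bout_frames = 20) {
  g <- eth$coarse == groom_class
  if (!any(g)) {
    message("no grooming frames; normalized modes undefined")
    return(tibble::tibble(mode = character(0), episodes = integer(0),
                          frames = integer(0), episode_fraction = numeric(0),
                          frame_fraction = numeric(0)))
  }
  fine_g <- unique(eth$fine[g])
  uncovered <- setdiff(as.character(fine_g), names(groom_submap))
  if (length(uncovered) > 0) {
    stop("groom_submap does not cover fine cluster(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  ## mode sequence over grooming stretches; non-groom breaks episodes
  modes_all <- unique(unname(groom_submap))
  eps <- tibble::tibble(mode = character(0), length = integer(0))
  for (run in split(which(g), cumsum(!g)[g])) {
    seq_modes <- unname(groom_submap[as.character(eth$fine[run])])
    seq_modes <- absorb_short_runs(seq_modes, min_bout_frames)
    r <- rle_runs(seq_modes)
    eps <- dplyr::bind_rows(eps, tibble::tibble(mode = r$value, length = r$length))
  }
  out <- eps |>
    dplyr::group_by(mode = factor(.data$mode, levels = modes_all)) |>
    dplyr::summarise(episodes = dplyr::n(), frames = sum(.data$length),
                     .groups = "drop") |>
    tidyr::complete(mode, fill = list(episodes = 0L, frames = 0L)) |>
    dplyr::mutate(mode = as.character(mode),
                  episode_fraction = .data$episodes / sum(.data$episodes),
                  frame_fraction = .data$frames / sum(.data$frames))
  out
}

#' Cohen's d with pooled standard deviation
#' @param a,b numeric samples.
#' @return effect size (mean(a) - mean(b)) / pooled SD.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(NA_real_)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Across-day habituation summary
#'
#' Per-class per-day group medians and the Cohen's d (pooled SD) between a
#' chosen pair of days.
#'
#' @param usage_long tidy usage tibble with columns `mouse`, `day`,
#'   `class`, `fraction`.
#' @param day_pair two days to contrast (default first vs last observed).
#' @return tibble: `class`, `day`, `median_fraction`, and per class a
#'   `cohens_d` for the day pair (repeated down the rows of that class).
#' @export
habituation_summary <- function(usage_long, day_pair = NULL) {
  stopifnot(all(c("mouse", "day", "class", "fraction") %in% names(usage_long)))
  days <- sort(unique(usage_long$day))
  if (length(days) < 2) stop("need at least 2 days", call. = FALSE)
  if (is.null(day_pair)) day_pair <- c(days[1], days[length(days)])
  med <- usage_long |>
    dplyr::group_by(.data$class, .data$day) |>
    dplyr::summarise(median_fraction = stats::median(.data$fraction),
                     n_mice = dplyr::n(), .groups = "drop")
  d <- usage_long |>
    dplyr::filter(.data$day %in% day_pair) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      cohens_d = cohens_d(.data$fraction[.data$day == day_pair[1]],
                          .data$fraction[.data$day == day_pair[2]]),
      .groups = "drop")
  if (any(is.na(d$cohens_d))) {
    message("Cohen's d undefined for groups with a single mouse")
  }
  dplyr::left_join(med, d, by = "class")
}
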