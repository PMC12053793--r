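CAUSE_LEVELS <- c("succession", "wind", "driftwood", "water")

SURVEY_COLUMNS <- c("plot_id", "dist_km", "x_m", "y_m",
                    "suitable_area_m2", "abundance")

#' Read a plot-occupancy survey table
#'
#' Reads one survey snapshot from CSV. Each row is one 5 x 5 m plot:
#' its identifier, along-coast distance to the range limit (km, 0 at the
#' limit and increasing toward the range core), projected planar
#' coordinates (m), the area of suitable habitat within the plot
#' (0--25 m^2), and the count of individuals. The optional
#' \code{causes} column carries semicolon-separated reasons why a plot
#' contains no suitable habitat (\code{succession}, \code{wind},
#' \code{driftwood}, \code{water}); the optional \code{is_dune} column
#' (0/1, default 1) marks whether the plot contains coastal dune
#' habitat at all.
#'
#' Rows violating the data model are rejected with row-indexed
#' messages: suitable area outside [0, 25], negative abundance,
#' abundance recorded on a non-dune plot, or unsuitability causes on a
#' plot that still has suitable habitat.
#'
#' @param path Path to a CSV file with a header row.
#' @param year Integer survey label stored alongside each record. If
#'   \code{NULL}, a \code{year} column must be present in the file.
#' @return A \code{data.frame} of validated plot records with a
#'   list-column \code{causes}.
#' @seealso [write_survey()], [pair_surveys()]
#' @export
read_survey <- function(path, year = NULL) {
  if (!file.exists(path)) stop_mr("survey file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(plot_id = "character"))
  missing_cols <- setdiff(SURVEY_COLUMNS, names(raw))
  if (length(missing_cols))
    stop_mr("survey file %s is missing required column(s): %s",
            path, paste(missing_cols, collapse = ", "))
  if (is.null(year)) {
    if (!"year" %in% names(raw))
      stop_mr("no `year` column in %s and no `year` argument given", path)
    year <- raw$year
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  as_survey(data.frame(
    plot_id = raw$plot_id,
    year = as.integer(year),
    dist_km = num(raw$dist_km),
    x_m = num(raw$x_m),
    y_m = num(raw$y_m),
    suitable_area_m2 = num(raw$suitable_area_m2),
    abundance = num(raw$abundance),
    stringsAsFactors = FALSE
  ), causes = parse_causes(raw$causes %||% rep("", nrow(raw))),
     is_dune = as.logical(raw$is_dune %||% rep(1L, nrow(raw))))
}

parse_causes <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(as.character(x), ";", fixed = TRUE),
         function(tok) {
           tok <- trimws(tok[nzchar(trimws(tok))])
           bad <- setdiff(tok, CAUSE_LEVELS)
           if (length(bad))
             stop_mr("unknown unsuitability cause(s): %s",
                     paste(bad, collapse = ", "))
           unique(tok)
         })
}

# Validate a survey data.frame against the plot data model; row-indexed
# messages so bad field records can be traced.
as_survey <- function(df, causes, is_dune) {
  n <- nrow(df)
  fail <- function(rows, what) {
    stop_mr("invalid survey record(s), row %s: %s",
            paste(utils::head(rows, 5L), collapse = ", "), what)
  }
  num_bad <- which(!is.finite(df$suitable_area_m2) | !is.finite(df$abundance))
  if (length(num_bad)) fail(num_bad, "non-numeric suitable_area_m2 or abundance")
  area_bad <- which(df$suitable_area_m2 < 0 | df$suitable_area_m2 > 25)
  if (length(area_bad)) fail(area_bad, "suitable_area_m2 outside [0, 25]")
  ab_bad <- which(df$abundance < 0 | df$abundance != round(df$abundance))
  if (length(ab_bad)) fail(ab_bad, "abundance must be a non-negative integer")
  if (anyNA(is_dune)) fail(which(is.na(is_dune)), "is_dune must be 0 or 1")
  dune_bad <- which(df$abundance > 0 & !is_dune)
  if (length(dune_bad)) fail(dune_bad, "abundance > 0 on a non-dune plot")
  cause_bad <- which(lengths(causes) > 0 & df$suitable_area_m2 > 0)
  if (length(cause_bad))
    fail(cause_bad, "unsuitability causes recorded on a plot with suitable habitat")
  df$abundance <- as.integer(df$abundance)
  df$causes <- causes
  df$is_dune <- is_dune
  class(df) <- c("plot_survey", "data.frame")
  df
}

#' Write a survey table to CSV
#'
#' Inverse of [read_survey()]: causes are serialized as
#' semicolon-separated tokens, \code{is_dune} as 0/1.
#'
#' @param x A survey \code{data.frame} as returned by [read_survey()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(x, path) {
  out <- x
  out$causes <- vapply(x$causes, paste, "", collapse = ";")
  out$is_dune <- as.integer(x$is_dune)
  class(out) <- "data.frame"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair two survey snapshots and classify transition events
#'
#' Joins the two snapshots on \code{plot_id}, drops plots that do not
#' contain coastal dune habitat in either year, and classifies each
#' remaining plot:
#' \itemize{
#' \item a \emph{colonisation candidate} is a plot unoccupied at the
#'   first survey and suitable (positive suitable area) at the second
#'   survey -- it need not have been suitable at the first survey;
#'   \code{colonised} records whether it is occupied at the second
#'   survey;
#' \item an \emph{extinction candidate} is any plot occupied at the
#'   first survey, regardless of suitability at the second survey;
#'   \code{extinct} records whether it is unoccupied at the second
#'   survey.
#' }
#' No plot can be both (candidacy is determined by first-survey
#' occupancy). Plots present in only one snapshot are excluded and
#' counted in the pairing log (\code{attr(x, "pairing_log")}).
#'
#' @param t1,t2 Survey \code{data.frame}s from [read_survey()] (first
#'   and second snapshot).
#' @return A \code{data.frame} of class \code{plot_pairs} with one row
#'   per paired dune plot: coordinates and distance, per-survey areas
#'   (\code{area_t1}, \code{area_t2}), abundances (\code{N_t1},
#'   \code{N_t2}), suitability and occupancy flags, candidate and event
#'   flags, and second-survey causes. The local-abundance covariate
#'   \code{L_t1} is filled by [local_abundance()].
#' @export
pair_surveys <- function(t1, t2) {
  for (nm in c("t1", "t2")) {
    s <- get(nm)
    dup <- unique(s$plot_id[duplicated(s$plot_id)])
    if (length(dup))
      stop_mr("duplicate plot_id within survey %s: %s",
              nm, paste(utils::head(dup, 5L), collapse = ", "))
  }
  common <- intersect(t1$plot_id, t2$plot_id)
  i1 <- match(common, t1$plot_id)
  i2 <- match(common, t2$plot_id)
  dune <- t1$is_dune[i1] & t2$is_dune[i2]
  log <- list(
    n_t1_only = length(setdiff(t1$plot_id, t2$plot_id)),
    n_t2_only = length(setdiff(t2$plot_id, t1$plot_id)),
    n_non_dune = sum(!dune),
    n_paired = sum(dune)
  )
  i1 <- i1[dune]; i2 <- i2[dune]
  pairs <- data.frame(
    plot_id = t1$plot_id[i1],
    dist_km = t1$dist_km[i1],
    x_m = t1$x_m[i1],
    y_m = t1$y_m[i1],
    area_t1 = t1$suitable_area_m2[i1],
    area_t2 = t2$suitable_area_m2[i2],
    N_t1 = t1$abundance[i1],
    N_t2 = t2$abundance[i2],
    stringsAsFactors = FALSE
  )
  pairs$suitable_t1 <- pairs$area_t1 > 0
  pairs$suitable_t2 <- pairs$area_t2 > 0
  pairs$occupied_t1 <- pairs$N_t1 >= 1L
  pairs$occupied_t2 <- pairs$N_t2 >= 1L
  pairs$L_t1 <- NA_real_
  pairs$colonisation_candidate <- !pairs$occupied_t1 & pairs$suitable_t2
  pairs$extinction_candidate <- pairs$occupied_t1
  pairs$colonised <- ifelse(pairs$colonisation_candidate, pairs$occupied_t2, NA)
  pairs$extinct <- ifelse(pairs$extinction_candidate, !pairs$occupied_t2, NA)
  pairs$causes_t2 <- t2$causes[i2]
  attr(pairs, "pairing_log") <- log
  class(pairs) <- c("plot_pairs", "data.frame")
  pairs
}

#' Local abundance within a neighbourhood radius
#'
#' For each plot, computes the first-survey local abundance \code{L_t1}:
#' the mean abundance over all \emph{other} plots whose planar Euclidean
#' distance from the focal plot is at most \code{radius_m}. Vacant
#' neighbours contribute zero counts to the mean; a plot with no
#' neighbour within the radius gets \code{NA} (and drops from covariate
#' models by complete-case filtering). The computation is exact
#' (pairwise distances), not grid-approximated.
#'
#' @param pairs A \code{plot_pairs} data.frame from [pair_surveys()].
#' @param radius_m Neighbourhood radius in metres (default 500, the
#'   scale over which seed dispersal has been recorded).
#' @return \code{pairs} with \code{L_t1} filled in.
#' @export
local_abundance <- function(pairs, radius_m = 500) {
  stopifnot(radius_m > 0)
  pairs$L_t1 <- local_mean(pairs$x_m, pairs$y_m, pairs$N_t1, radius_m)
  pairs
}

# Exact mean of `value` over all other points within `radius` of each
# point. Sorted sweep over x keeps it O(n * k) for k neighbours in the
# x-window rather than O(n^2).
local_mean <- function(x, y, value, radius) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]; vs <- value[ord]
  lo <- findInterval(xs - radius, xs) + 1L
  hi <- findInterval(xs + radius, xs)
  out <- rep(NA_real_, n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    j <- j[j != i]
    if (!length(j)) next
    keep <- (xs[j] - xs[i])^2 + (ys[j] - ys[i])^2 <= r2
    if (any(keep)) out[i] <- mean(vs[j[keep]])
  }
  res <- rep(NA_real_, n)
  res[ord] <- out
  res
}

#' Summarise colonisation and extinction events
#'
#' Counts candidate pools and realized events, and reports the crude
#' (pooled) colonisation and extinction rates together with occupancy
#' at both surveys, over all plots and over suitable plots only.
#'
#' @param pairs A \code{plot_pairs} data.frame.
#' @return An object of class \code{event_summary}: a list with
#'   \code{n_candidates_col}, \code{n_events_col}, \code{crude_c},
#'   \code{n_candidates_ext}, \code{n_events_ext}, \code{crude_e},
#'   \code{occupancy_t1}, \code{occupancy_t2},
#'   \code{occupancy_suitable_t1}, \code{occupancy_suitable_t2}. A
#'   crude rate over an empty pool is \code{NA}, not zero.
#' @export
summarize_events <- function(pairs) {
  rate <- function(events, pool) if (pool == 0L) NA_real_ else events / pool
  ncc <- sum(pairs$colonisation_candidate)
  nec <- sum(pairs$colonised, na.rm = TRUE)
  nce <- sum(pairs$extinction_candidate)
  nee <- sum(pairs$extinct, na.rm = TRUE)
  out <- list(
    n_candidates_col = ncc, n_events_col = nec, crude_c = rate(nec, ncc),
    n_candidates_ext = nce, n_events_ext = nee, crude_e = rate(nee, nce),
    occupancy_t1 = mean(pairs$occupied_t1),
    occupancy_t2 = mean(pairs$occupied_t2),
    occupancy_suitable_t1 = if (any(pairs$suitable_t1))
      mean(pairs$occupied_t1[pairs$suitable_t1]) else NA_real_,
    occupancy_suitable_t2 = if (any(pairs$suitable_t2))
      mean(pairs$occupied_t2[pairs$suitable_t2]) else NA_real_
  )
  class(out) <- "event_summary"
  out
}

#' @export
print.event_summary <- function(x, ...) {
  cat("Colonisation: ", x$n_events_col, "/", x$n_candidates_col,
      " suitable-but-vacant plots (c = ", fmt3(x$crude_c), ")\n", sep = "")
  cat("Extinction:   ", x$n_events_ext, "/", x$n_candidates_ext,
      " occupied plots (e = ", fmt3(x$crude_e), ")\n", sep = "")
  cat("Occupancy (all plots):      t1 ", fmt3(x$occupancy_t1),
      ", t2 ", fmt3(x$occupancy_t2), "\n", sep = "")
  cat("Occupancy (suitable plots): t1 ", fmt3(x$occupancy_suitable_t1),
      ", t2 ", fmt3(x$occupancy_suitable_t2), "\n", sep = "")
  invisible(x)
}

fmt3 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 3, format = "f"))

#' Classify extinction outcomes as demographic or environmental
#'
#' For every extinction event, reports whether the plot still contained
#' suitable habitat at the second survey (a demographic extinction) or
#' had become unsuitable (an environmental extinction), and passes
#' through the recorded causes of unsuitability (a plot may have
#' several). Unsuitable plots with no recorded cause are flagged
#' \code{cause_missing} and excluded from the summary proportions,
#' which are attached as attributes: \code{prop_still_suitable} (over
#' the complete-cause subset) and \code{cause_props} (per-cause share
#' among environmental extinctions; shares can sum to more than 1).
#'
#' @param pairs A \code{plot_pairs} data.frame.
#' @return A \code{data.frame} with one row per extinct plot:
#'   \code{plot_id}, \code{dist_km}, \code{still_suitable},
#'   \code{cause_missing}, and list-column \code{causes}.
#' @export
classify_extinction_outcomes <- function(pairs) {
  ext <- pairs[which(pairs$extinct), , drop = FALSE]
  out <- data.frame(plot_id = ext$plot_id, dist_km = ext$dist_km,
                    still_suitable = ext$suitable_t2,
                    stringsAsFactors = FALSE)
  out$causes <- ext$causes_t2
  out$cause_missing <- !out$still_suitable & lengths(out$causes) == 0L
  complete <- !out$cause_missing
  unsuit <- complete & !out$still_suitable
  attr(out, "n_extinct") <- nrow(out)
  attr(out, "n_complete") <- sum(complete)
  attr(out, "prop_still_suitable") <-
    if (any(complete)) sum(out$still_suitable[complete]) / sum(complete) else NA_real_
  attr(out, "cause_props") <- if (any(unsuit)) {
    vapply(CAUSE_LEVELS, function(k)
      mean(vapply(out$causes[unsuit], function(cs) k %in% cs, NA)), 0)
  } else {
    stats::setNames(rep(NA_real_, length(CAUSE_LEVELS)), CAUSE_LEVELS)
  }
  out
}

#' Write paired-event records to CSV
#'
#' All \code{plot_pairs} fields; missing values (for example \code{L_t1}
#' for isolated plots, or event flags outside their candidate pool) are
#' serialized as empty fields, causes as semicolon-separated tokens.
#'
#' @param pairs A \code{plot_pairs} data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  out <- pairs
  out$causes_t2 <- vapply(pairs$causes_t2, paste, "", collapse = ";")
  for (nm in c("suitable_t1", "suitable_t2", "occupied_t1", "occupied_t2",
               "colonisation_candidate", "extinction_candidate",
               "colonised", "extinct"))
    out[[nm]] <- as.integer(out[[nm]])
  class(out) <- "data.frame"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
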