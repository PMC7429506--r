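#' Read long-format interaction records
#'
#' Parses a delimited text file of plant-pollinator interaction events. Each
#' row is one (season, week, plant, pollinator) combination together with the
#' number of interaction events observed for it that week.
#'
#' @param path path to a delimited text file with a header row.
#' @param cols named character vector mapping the canonical field names
#'   (`season`, `week`, `plant`, `pollinator`, `count`) to the column names
#'   used in the file.
#' @param sep field separator (default `","`).
#' @return A `data.frame` with columns `season`, `week`, `plant`,
#'   `pollinator`, `count`. Extra columns in the file are ignored.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(season = "S1", week = 1, plant = "P1",
#'                      pollinator = "A1", count = 2), f, row.names = FALSE)
#' load_records(f)
#' @export
load_records <- function(path,
                         cols = c(season = "season", week = "week",
                                  plant = "plant", pollinator = "pollinator",
                                  count = "count"),
                         sep = ",") {
  need <- c("season", "week", "plant", "pollinator", "count")
  if (!all(need %in% names(cols)))
    stop("`cols` must name all of: ", paste(need, collapse = ", "))
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  missing <- setdiff(unname(cols[need]), names(raw))
  if (length(missing))
    stop("configuration error: column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "))
  rec <- data.frame(season = as.character(raw[[cols["season"]]]),
                    week = suppressWarnings(as.integer(raw[[cols["week"]]])),
                    plant = as.character(raw[[cols["plant"]]]),
                    pollinator = as.character(raw[[cols["pollinator"]]]),
                    count = suppressWarnings(as.numeric(raw[[cols["count"]]])),
                    stringsAsFactors = FALSE)
  validate_records(rec, line_offset = 1L)
  rec$count <- as.integer(rec$count)
  rec
}

# shared validation; line_offset accounts for a header line when reporting
validate_records <- function(rec, line_offset = 0L) {
  bad <- which(is.na(rec$count) | rec$count < 1 |
                 rec$count != round(rec$count) |
                 is.na(rec$week) | rec$week < 1 |
                 is.na(rec$plant) | !nzchar(rec$plant) |
                 is.na(rec$pollinator) | !nzchar(rec$pollinator))
  if (length(bad))
    stop("validation error: malformed record(s) at line(s) ",
         paste(bad + line_offset, collapse = ", "),
         " (count and week must be positive integers; taxon labels non-empty)")
  invisible(rec)
}

#' Construct a weekly weighted bipartite network
#'
#' @param season season identifier.
#' @param week positive integer week index within the season.
#' @param edges `data.frame` with columns `plant`, `pollinator`, `weight`;
#'   one row per interacting species pair, positive integer weights.
#' @return An object of class `weekly_network`.
#' @export
weekly_network <- function(season, week, edges) {
  stopifnot(is.data.frame(edges),
            all(c("plant", "pollinator", "weight") %in% names(edges)))
  if (nrow(edges) == 0) stop("a weekly network must have at least one edge")
  if (any(edges$weight < 1 | edges$weight != round(edges$weight)))
    stop("edge weights must be positive integers")
  if (anyDuplicated(edges[c("plant", "pollinator")]))
    stop("duplicate (plant, pollinator) edge")
  edges <- edges[order(edges$plant, edges$pollinator), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(season = as.character(season), week = as.integer(week),
                 edges = edges),
            class = "weekly_network")
}

#' @export
print.weekly_network <- function(x, ...) {
  cat(sprintf("<weekly_network %s: %d plants, %d pollinators, %d edges, total weight %d>\n",
              network_id(x), length(unique(x$edges$plant)),
              length(unique(x$edges$pollinator)), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Identifier of a weekly network ("season.wWW")
#' @param net a `weekly_network`.
#' @return character scalar.
#' @export
network_id <- function(net) sprintf("%s.w%02d", net$season, net$week)

#' Species present in a weekly network
#' @param net a `weekly_network`.
#' @param guild `"both"`, `"plant"` or `"pollinator"`.
#' @return character vector of species labels (sorted).
#' @export
network_species <- function(net, guild = c("both", "plant", "pollinator")) {
  guild <- match.arg(guild)
  p <- sort(unique(net$edges$plant))
  a <- sort(unique(net$edges$pollinator))
  switch(guild, both = c(p, a), plant = p, pollinator = a)
}

#' Guild membership of every species of a network
#' @param net a `weekly_network`.
#' @return Named character vector (`"plant"`/`"pollinator"`) keyed by
#'   species, plants first.
#' @export
network_guilds <- function(net) {
  p <- sort(unique(net$edges$plant))
  a <- sort(unique(net$edges$pollinator))
  setNames(c(rep("plant", length(p)), rep("pollinator", length(a))), c(p, a))
}

#' Aggregate interaction records into weekly network time series
#'
#' Sums interaction counts per (season, week, plant, pollinator) and builds
#' one weighted bipartite network per sampled week. Weeks with no records are
#' simply absent from the series (no empty-week padding); species appear in a
#' week only if they interacted at least once that week.
#'
#' @param records a `data.frame` of interaction records as returned by
#'   [load_records()].
#' @return A named list (one element per season) of `network_series` objects:
#'   each carries `season`, `networks` (weekly networks in increasing week
#'   order) and `W`, the number of sampled weeks.
#' @export
aggregate_weekly <- function(records) {
  validate_records(records)
  agg <- aggregate(count ~ season + week + plant + pollinator, data = records,
                   FUN = sum)
  out <- list()
  for (s in sort(unique(agg$season))) {
    sa <- agg[agg$season == s, , drop = FALSE]
    weeks <- sort(unique(sa$week))
    nets <- lapply(weeks, function(w) {
      e <- sa[sa$week == w, c("plant", "pollinator", "count")]
      names(e)[3] <- "weight"
      weekly_network(s, w, e)
    })
    out[[s]] <- structure(list(season = s, networks = nets,
                               W = length(weeks)),
                          class = "network_series")
  }
  out
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("<network_series %s: %d weekly networks (weeks %s)>\n",
              x$season, x$W,
              paste(vapply(x$networks, function(n) n$week, 1L), collapse = ",")))
  invisible(x)
}

#' Binarize a network or series
#'
#' Sets the weight of every interaction to a common value of 1, preserving
#' topology exactly. Idempotent.
#'
#' @param x a `weekly_network` or `network_series`.
#' @return Object of the same class with all edge weights equal to 1.
#' @export
to_binary <- function(x) UseMethod("to_binary")

#' @export
to_binary.weekly_network <- function(x) {
  x$edges$weight <- rep(1L, nrow(x$edges))
  x
}

#' @export
to_binary.network_series <- function(x) {
  x$networks <- lapply(x$networks, to_binary)
  x
}

#' Flat index of weekly networks across seasons
#'
#' @param series_list named list of `network_series` (as from
#'   [aggregate_weekly()]).
#' @return Named list of `weekly_network` objects keyed by [network_id()].
#' @export
network_index <- function(series_list) {
  nets <- unlist(lapply(series_list, function(s) s$networks),
                 recursive = FALSE)
  setNames(nets, vapply(nets, network_id, ""))
}

#' Write per-week edge lists as CSV
#'
#' @param series_list named list of `network_series`.
#' @param path output file.
#' @return Invisibly, the exported `data.frame` (season, week, plant,
#'   pollinator, weight).
#' @export
write_weekly_edges <- function(series_list, path) {
  rows <- do.call(rbind, lapply(network_index(series_list), function(net) {
    cbind(season = net$season, week = net$week, net$edges)
  }))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}

#' Pipeline configuration
#'
#' Returns the full set of stage parameters used by the pipeline, optionally
#' read from a YAML file and/or overridden by name. Every stage function also
#' accepts these settings directly; the configuration object is a convenience
#' for scripted runs.
#'
#' @param path optional YAML file whose top-level keys override the defaults.
#' @param ... further named overrides (applied after the file).
#' @return A named list of parameters with class `netweave_config`.
#' @export
netweave_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    motif_sizes = c(3L, 5L),
    role_mode = "weighted",      # weighted | binary
    weight_stat = "mean",        # mean | sum | gmean
    role_normalization = "none", # none | unit_sum | zscore
    n_align = 100L,
    unpaired_penalty = 1.0,
    anneal = list(t0 = 1.0, cooling = 0.995, sweeps = 500L),
    quality_weighting = "frequency_x_correlation",
    walktrap_steps = 4L,
    nmi_normalization = "mean",
    prior_sd = 10,
    chains = 4L,
    iter = 2500L,
    warmup = 1000L
  )
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "netweave_config")
}
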