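#' Read a count table
#'
#' Reads the CSV schema used throughout: columns \code{name}, \code{time}
#' (days), \code{count}, then zero or more sampling-fraction columns
#' \code{sample1}, \code{sample2}, ... Column names are matched
#' case-insensitively; a missing fraction column set defaults to a single
#' stage of 1.0 (the counts are whole-population counts). Rows are grouped by
#' name and sorted by time. Validation is strict: negative or non-numeric
#' counts, fractions outside (0, 1] and duplicate times within a series are
#' errors with row-numbered messages.
#'
#' @param path path to a CSV file with a header row, comma separator, "."
#'   decimal mark.
#' @return a named list of \code{\link{count_series}} objects.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  for (col in c("name", "time", "count"))
    if (!col %in% names(raw)) stop("count file is missing required column '", col, "'")
  if (nrow(raw) == 0) stop("no records in count file ", path)
  frac_cols <- grep("^sample[0-9]+$", names(raw), value = TRUE)
  frac_cols <- frac_cols[order(as.integer(sub("sample", "", frac_cols)))]

  check_numeric <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric or missing '", col, "' at data row(s) ",
           paste(bad, collapse = ", "))
    v
  }
  time <- check_numeric("time")
  count <- check_numeric("count")
  bad <- which(count < 0 | count != round(count))
  if (length(bad))
    stop("counts must be non-negative integers; bad row(s) ",
         paste(bad, collapse = ", "))
  if (length(frac_cols)) {
    fr <- vapply(frac_cols, check_numeric, numeric(nrow(raw)))
    fr <- matrix(fr, nrow = nrow(raw))
    bad <- which(apply(fr <= 0 | fr > 1, 1, any))
    if (length(bad))
      stop("sampling fractions must lie in (0, 1]; bad row(s) ",
           paste(bad, collapse = ", "))
  } else {
    fr <- matrix(1, nrow = nrow(raw), ncol = 1)
  }

  out <- lapply(split(seq_len(nrow(raw)), as.character(raw$name)), function(idx) {
    count_series(as.character(raw$name[idx[1]]), time[idx], count[idx],
                 fr[idx, , drop = FALSE])
  })
  out[order(names(out))]
}

#' Write a count table
#'
#' Inverse of \code{\link{read_counts}}: writes one or more series back to
#' the same CSV schema, round-tripping records exactly.
#'
#' @param series a \code{count_series} or list of them.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_counts <- function(series, path) {
  if (inherits(series, "count_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal TOML-subset reader -------------------------------------------
# Supports: comments (#), [section] tables, key = value with values that are
# numbers (incl. scientific notation), booleans, quoted strings, and flat
# arrays of those. Sufficient for the run-configuration format; no installed
# package parses TOML.
parse_toml_value <- function(txt) {
  txt <- trimws(txt)
  if (startsWith(txt, "[")) {
    inner <- sub("^\\[", "", sub("\\]$", "", txt))
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",(?=(?:[^\"]*\"[^\"]*\")*[^\"]*$)", perl = TRUE)[[1]]
    return(lapply(parts, parse_toml_value))
  }
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (grepl("^'.*'$", txt)) return(gsub("^'|'$", "", txt))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(gsub("_", "", txt)))
  if (!is.na(num)) return(num)
  stop("cannot parse TOML value: ", txt)
}

read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub('#(?=(?:[^"]*"[^"]*")*[^"]*$).*$', "", lines[i], perl = TRUE)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- strsplit(gsub("^\\[|\\]$", "", ln), ".", fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line ", i, ": ", lines[i])
    key <- trimws(substr(ln, 1, eq - 1))
    val <- parse_toml_value(substr(ln, eq + 1, nchar(ln)))
    v <- if (is.list(val)) simplify_toml_array(val) else val
    if (length(section) == 0) {
      out[[key]] <- v
    } else {
      node <- paste(section, collapse = ".")
      if (is.null(out[[node]])) out[[node]] <- list()
      out[[node]][[key]] <- v
    }
  }
  out
}

simplify_toml_array <- function(x) {
  if (all(vapply(x, is.numeric, TRUE))) return(unlist(x))
  if (all(vapply(x, is.character, TRUE))) return(unlist(x))
  x
}

#' Read a run configuration
#'
#' Parses the TOML-format configuration. The only required key is
#' \code{carrying_capacity}; everything else has a sensible default:
#' rate prior (0.01, 3.0) divisions/day, control-point counts \{1, 2, 3\},
#' deterministic simulator, miscount probability 0.05, 200 particles over 6
#' SMC generations with a 0.5 epsilon quantile, 4 parallel workers. Unknown
#' keys trigger a warning; a missing carrying capacity is an error. Grouping
#' is given as a \code{[groups]} table mapping group name to an array of
#' series names.
#'
#' @param path path to a TOML config file.
#' @return a \code{run_config} list with elements \code{carrying_capacity},
#'   \code{prior} (\code{\link{prior_spec}}), \code{abc}
#'   (\code{\link{abc_config}}), \code{noise} (\code{\link{counting_noise}}),
#'   and \code{groups}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  toml <- read_toml(path)
  known <- c("carrying_capacity", "rate_min", "rate_max", "control_points",
             "simulator", "p_wrong", "n_particles", "n_generations",
             "epsilon_quantile", "distance", "n_parallel", "seed", "groups")
  unknown <- setdiff(names(toml), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(toml$carrying_capacity))
    stop("config must set the carrying capacity (key 'carrying_capacity')")
  get <- function(key, default) if (is.null(toml[[key]])) default else toml[[key]]
  prior <- prior_spec(rate_min = get("rate_min", 0.01),
                      rate_max = get("rate_max", 3.0),
                      control_points = get("control_points", c(1, 2, 3)))
  abc <- abc_config(n_particles = get("n_particles", 200),
                    n_generations = get("n_generations", 6),
                    epsilon_quantile = get("epsilon_quantile", 0.25),
                    distance = get("distance", "sqrt_euclid"),
                    simulator = get("simulator", "deterministic"),
                    n_parallel = get("n_parallel", 4),
                    seed = get("seed", 1))
  noise <- if (get("p_wrong", 0.05) == 0) counting_noise("none")
           else counting_noise("normal_binomial", get("p_wrong", 0.05))
  groups <- toml$groups
  if (!is.null(groups) && !is.list(groups)) groups <- as.list(groups)
  structure(list(carrying_capacity = toml$carrying_capacity,
                 prior = prior, abc = abc, noise = noise,
                 groups = groups),
            class = "run_config")
}

#' Group count series for joint fitting
#'
#' Series in the same group are fitted jointly: one shared rate curve with an
#' independent initial population per series (replicate semantics). Series
#' not mentioned in the grouping form singleton groups. Groups must partition
#' the series: a series in two groups, or a grouping that references an
#' unknown series, is an error.
#'
#' @param series named list of \code{\link{count_series}}.
#' @param grouping named list mapping group label to a character vector of
#'   series names, or NULL for the identity partition.
#' @return a named list of groups, each a list of \code{count_series}.
#' @export
group_series <- function(series, grouping = NULL) {
  stopifnot(is.list(series))
  nm <- vapply(series, function(s) s$name[1], character(1))
  names(series) <- nm
  if (is.null(grouping) || length(grouping) == 0)
    return(lapply(stats::setNames(nm, nm), function(n) series[n]))
  members <- unlist(grouping, use.names = FALSE)
  unknown <- setdiff(members, nm)
  if (length(unknown))
    stop("grouping references unknown series: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(members))
    stop("series assigned to more than one group: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  out <- lapply(grouping, function(ms) series[ms])
  leftover <- setdiff(nm, members)
  out <- c(out, lapply(stats::setNames(leftover, leftover), function(n) series[n]))
  out
}
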