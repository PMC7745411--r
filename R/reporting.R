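#' Summarise a posterior as a fit table
#'
#' One row per (group, model, parameter): the weighted posterior mean,
#' median, 89% HPDI bounds and the model's posterior probability. Rate
#' control points appear as \code{r1}, \code{r2}, ... with their control
#' times (days, on the original data timescale); per-series initial
#' populations as \code{n0:<series>}.
#'
#' @param post an \code{abc_posterior}.
#' @param group label for the group column; defaults to the joined series
#'   names.
#' @param mass HPD mass (default 0.89).
#' @return a data frame with columns \code{group}, \code{model},
#'   \code{parameter}, \code{time}, \code{mean}, \code{median},
#'   \code{hpdi_low}, \code{hpdi_high}, \code{model_probability}.
#' @export
fit_table <- function(post, group = NULL, mass = 0.89) {
  stopifnot(inherits(post, "abc_posterior"))
  if (is.null(group))
    group <- paste(vapply(post$series, function(s) s$name[1], character(1)),
                   collapse = "+")
  rows <- list()
  for (m in post$models) {
    if (is.null(m$samples)) next
    k <- m$k
    ctimes <- if (k == 1) post$t0
              else post$t0 + seq(0, post$t_span, length.out = k)
    pnames <- colnames(m$samples)
    ptimes <- c(rep(NA_real_, ncol(m$samples) - k), ctimes)
    for (j in seq_len(ncol(m$samples))) {
      x <- m$samples[, j]
      h <- hpdi(x, mass = mass, weights = m$weights)
      rows[[length(rows) + 1]] <- data.frame(
        group = group, model = k, parameter = pnames[j], time = ptimes[j],
        mean = sum(x * m$weights), median = weighted_quantile(x, m$weights, 0.5),
        hpdi_low = h$low, hpdi_high = h$high,
        model_probability = m$probability)
    }
  }
  do.call(rbind, rows)
}

#' Write a fit table to CSV
#'
#' Comma-separated, header row, UTF-8, "." decimal; values round-trip at full
#' precision through \code{read.csv}.
#'
#' @param post an \code{abc_posterior} (or a data frame already produced by
#'   \code{\link{fit_table}}).
#' @param path output path.
#' @param ... passed to \code{\link{fit_table}}.
#' @return the path, invisibly.
#' @export
write_fit_table <- function(post, path, ...) {
  tab <- if (is.data.frame(post)) post else fit_table(post, ...)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Numeric series behind the report panels
#'
#' Everything the report figure draws, exposed as plain numbers so the plot
#' content can be tested independently of rendering: the observed counts as
#' population point estimates, the posterior-median population curve with its
#' HPD band per series, the rate curve band, and the raincloud components
#' (weighted kernel density grid, weighted quartiles, raw samples) of each
#' control point of the highest-probability model.
#'
#' @param post an \code{abc_posterior}.
#' @param times evaluation grid; default 101 points over the data window.
#' @param mass HPD mass (default 0.89).
#' @return list with \code{observations}, \code{population}, \code{rate},
#'   \code{raincloud}, \code{top_model}.
#' @export
report_panels <- function(post, times = NULL, mass = 0.89) {
  stopifnot(inherits(post, "abc_posterior"))
  bands <- posterior_rate_band(post, times = times, mass = mass)
  obs <- do.call(rbind, lapply(post$series, function(s) {
    fm <- fraction_matrix(s)
    data.frame(series = s$name[1], time = s$time,
               estimate = s$count / apply(fm, 1, prod))
  }))
  top <- names(which.max(post$model_prob))
  tm <- post$models[[top]]
  k <- tm$k
  ctimes <- if (k == 1) post$t0 else post$t0 + seq(0, post$t_span, length.out = k)
  rain <- lapply(seq_len(k), function(j) {
    x <- tm$samples[, ncol(tm$samples) - k + j]
    w <- tm$weights / sum(tm$weights)
    bw <- if (length(unique(x)) > 1) stats::bw.nrd0(x) else 0.01
    dens <- stats::density(x, weights = w, bw = bw)
    list(control_point = j, time = ctimes[j],
         density = data.frame(x = dens$x, y = dens$y),
         quartiles = stats::setNames(
           vapply(c(0.25, 0.5, 0.75), function(p) weighted_quantile(x, w, p),
                  numeric(1)),
           c("q25", "q50", "q75")),
         samples = x, weights = w)
  })
  list(observations = obs, population = bands$population, rate = bands$rate,
       raincloud = rain, top_model = as.integer(top))
}

#' Render the report figure
#'
#' Two stacked panels in the style of the tool's standard report: the top
#' panel shows observed counts as population point estimates over the
#' posterior-median population curve and its shaded 89% HPD band (one facet
#' per series); the bottom panel shows the inferred rate curve with dashed
#' HPD bounds and a connected raincloud (kernel density, box quartiles,
#' jittered samples) at each control point of the most probable model. The
#' output format is chosen by the file extension (pdf, png, svg, ...).
#'
#' @param post an \code{abc_posterior}.
#' @param path output figure file.
#' @param mass HPD mass (default 0.89).
#' @return the path, invisibly.
#' @export
plot_report <- function(post, path, mass = 0.89) {
  pan <- report_panels(post, mass = mass)
  popdf <- do.call(rbind, lapply(names(pan$population), function(nm) {
    cbind(series = nm, pan$population[[nm]])
  }))
  p_top <- ggplot2::ggplot(popdf, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "black") +
    ggplot2::geom_point(data = pan$observations,
                        ggplot2::aes(y = .data$estimate), size = 1.6) +
    ggplot2::facet_wrap(~series) +
    ggplot2::labs(x = "time [days]", y = "population [cells]") +
    ggplot2::theme_minimal()

  rainpts <- do.call(rbind, lapply(pan$raincloud, function(r) {
    data.frame(time = r$time, rate = r$samples, weight = r$weights)
  }))
  quart <- do.call(rbind, lapply(pan$raincloud, function(r) {
    data.frame(time = r$time, q25 = r$quartiles["q25"],
               q50 = r$quartiles["q50"], q75 = r$quartiles["q75"])
  }))
  p_bot <- ggplot2::ggplot(pan$rate, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$low), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$high), linetype = "dashed") +
    ggplot2::geom_jitter(data = rainpts,
                         ggplot2::aes(y = .data$rate, alpha = .data$weight),
                         width = 0.08, size = 0.5, colour = "grey40") +
    ggplot2::geom_errorbar(data = quart,
                           ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                           width = 0.15) +
    ggplot2::geom_point(data = quart, ggplot2::aes(y = .data$q50), size = 2) +
    ggplot2::guides(alpha = "none") +
    ggplot2::labs(x = "time [days]", y = "growth rate [divisions/day]") +
    ggplot2::theme_minimal()

  fig <- patchwork::wrap_plots(p_top, p_bot, ncol = 1)
  ggplot2::ggsave(path, fig, width = 7, height = 7)
  invisible(path)
}
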