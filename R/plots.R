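# Reproducible versions of the study's result figures, from any derived
# analysis table.

#' @import ggplot2
NULL

#' Histogram of weekly-averaged exposure levels
#'
#' Distribution of the weekly-averaged noise-exposure level among ear-piece
#' users, with the 85 dBA Upper Exposure Action Value marked.
#'
#' @param data Derived analysis table.
#' @return A ggplot object.
#' @export
plot_weekly_levels <- function(data) {
  users <- data[data$device_use != "nonuser" & !is.na(data$weekly_level), ]
  ggplot(users, aes(x = .data$weekly_level)) +
    geom_histogram(binwidth = 1, fill = "grey55", colour = "white") +
    geom_vline(xintercept = 85, linetype = "dotted", colour = "red") +
    labs(x = "Weekly-averaged noise-exposure level (dBA)",
         y = "Ear-piece users") +
    theme_minimal()
}

#' Volume-control settings by TTS frequency
#'
#' Boxplots of the energy-weighted average volume-control setting for the
#' five TTS-frequency response groups.
#'
#' @param data Derived analysis table.
#' @return A ggplot object.
#' @export
plot_volume_by_tts <- function(data) {
  users <- data[!is.na(data$tts_prop) & !is.na(data$volume_average), ]
  users$tts_prop <- factor(users$tts_prop, levels = tts_levels())
  ggplot(users, aes(x = .data$tts_prop, y = .data$volume_average)) +
    geom_boxplot(outlier.shape = NA, coef = 1.5) +
    labs(x = "Frequency of signs of TTS after ear-piece use",
         y = "Average volume-control setting (%)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
}

#' Tinnitus prevalence by exposure group
#'
#' Prevalence of prolonged spontaneous tinnitus (a) in users vs nonusers and
#' (b) across TTS-instance groups, with unadjusted binomial 95% CIs.
#'
#' @param data Derived analysis table.
#' @return A ggplot object.
#' @export
plot_tinnitus_prevalence <- function(data) {
  prev_ci <- function(x) {
    n <- length(x); p <- mean(x)
    se <- sqrt(p * (1 - p) / n)
    data.frame(prev = 100 * p, lo = 100 * (p - 1.96 * se),
               hi = 100 * (p + 1.96 * se))
  }
  d1 <- do.call(rbind, lapply(split(data$tin_long,
                                    ifelse(data$device_use == "nonuser",
                                           "nonuser", "user")), prev_ci))
  d1$group <- rownames(d1); d1$panel <- "By ear-piece use"
  users <- data[!is.na(data$tts_group), ]
  d2 <- do.call(rbind, lapply(split(users$tin_long, users$tts_group), prev_ci))
  d2$group <- rownames(d2); d2$panel <- "By TTS instances (users)"
  dd <- rbind(d1, d2)
  dd$group <- factor(dd$group, levels = c("nonuser", "user", "none", "1-100", ">100"))
  ggplot(dd, aes(x = .data$group, y = .data$prev)) +
    geom_col(fill = "grey55") +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    facet_grid(~panel, scales = "free_x", space = "free_x") +
    labs(x = NULL, y = "Prolonged spontaneous tinnitus (%)") +
    theme_minimal()
}

#' Tinnitus location by exposure side
#'
#' Prevalence of central / right / left tinnitus within nonusers,
#' right-sided users and left-sided users.
#'
#' @param data Derived analysis table.
#' @return A ggplot object.
#' @export
plot_tinnitus_location <- function(data) {
  grp <- ifelse(data$device_use == "nonuser", "nonuser",
                ifelse(data$device_use == "unilateral" & !is.na(data$device_side),
                       paste0(data$device_side, "-sided user"), NA))
  d <- data[!is.na(grp), ]
  grp <- grp[!is.na(grp)]
  tab <- as.data.frame(prop.table(table(group = grp,
                                        location = d$tin_location), 1))
  tab <- tab[tab$location != "none", ]
  tab$location <- factor(tab$location,
                         levels = c("central", "right_only_or_mainly",
                                    "left_only_or_mainly"),
                         labels = c("central", "only/mainly right",
                                    "only/mainly left"))
  ggplot(tab, aes(x = .data$group, y = 100 * .data$Freq, fill = .data$location)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "Prevalence (%)", fill = "Tinnitus location") +
    theme_minimal()
}

#' Digits-in-noise threshold distributions
#'
#' Boxplots of monaural thresholds for exposed and control ears of users and
#' both-ear averages of nonusers, plus the between-ear difference measure in
#' users.
#'
#' @param data Derived analysis table.
#' @return A ggplot object.
#' @export
plot_din_distributions <- function(data) {
  d <- data[!is.na(data$din_right) & !is.na(data$din_left), ]
  user <- d$device_use == "unilateral" & !is.na(d$device_side)
  exposed <- ifelse(d$device_side[user] == "right", d$din_right[user],
                    d$din_left[user])
  control <- ifelse(d$device_side[user] == "right", d$din_left[user],
                    d$din_right[user])
  nonuser_avg <- (d$din_right + d$din_left)[d$device_use == "nonuser"] / 2
  long <- rbind(
    data.frame(measure = "exposed ear (users)", value = exposed),
    data.frame(measure = "control ear (users)", value = control),
    data.frame(measure = "both-ear mean (nonusers)", value = nonuser_avg),
    data.frame(measure = "DigitsDiff (users)",
               value = d$digits_diff[user & !is.na(d$digits_diff)])
  )
  ggplot(long, aes(x = .data$measure, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, coef = 1.5) +
    labs(x = NULL, y = "DIN threshold / difference (dB SNR)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 20, hjust = 1))
}

#' Write the result figures to files
#'
#' @param data Derived analysis table.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_figures <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  figs <- list(
    fig1_weekly_levels = plot_weekly_levels,
    fig2_volume_by_tts = plot_volume_by_tts,
    fig3_tinnitus_prevalence = plot_tinnitus_prevalence,
    fig4_tinnitus_location = plot_tinnitus_location,
    fig5_din_distributions = plot_din_distributions
  )
  paths <- character(0)
  for (nm in names(figs)) {
    p <- file.path(dir, paste0(nm, ".pdf"))
    g <- try(figs[[nm]](data), silent = TRUE)
    if (!inherits(g, "try-error")) {
      ggplot2::ggsave(p, g, width = 7, height = 5)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
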