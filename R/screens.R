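#' Configuration for the screening drivers
#'
#' Bundles everything the four screens need: which modules to run, the
#' anchor drug target, the combination partners, the dose, the stimulus,
#' the integration settings, the crosstalk-scale grid for strength scans
#' and the synergy-classification tolerance. Module 0 is always simulated
#' (it is the baseline of the efficacy index) even when left out of
#' `modules`.
#'
#' @param modules Integer subset of 0..8 (default: all).
#' @param anchor_target Species targeted by the anchor drug (default `"B"`).
#' @param partner_targets Partners screened in combination with the anchor
#'   (default A, B, C, D).
#' @param dose Anchor drug dose (> 0; default 1).
#' @param partner_dose Partner drug dose (default: same as `dose`).
#' @param stimulus Name of the stimulus pair applied to both channels
#'   (default `"S0"`).
#' @param horizon,h Integration horizon and RK4 step (defaults 100 and 0.01).
#' @param crosstalk_scale Crosstalk strength multiplier for single runs
#'   (default 1).
#' @param scale_grid Strictly positive grid of crosstalk scales for
#'   [strength_scan()] (default: 8 geometric points from 1 to 10).
#' @param tol Synergy classification tolerance (default 0.05).
#' @param inhibition Inhibition-term convention passed to the integrator.
#' @return A validated object of class `screen_config`.
#' @export
screen_config <- function(modules = 0:8,
                          anchor_target = "B",
                          partner_targets = c("A", "B", "C", "D"),
                          dose = 1,
                          partner_dose = dose,
                          stimulus = "S0",
                          horizon = 100,
                          h = 0.01,
                          crosstalk_scale = 1,
                          scale_grid = 10^seq(0, 1, length.out = 8L),
                          tol = 0.05,
                          inhibition = c("deactivation", "literal")) {
  inhibition <- match.arg(inhibition)
  modules <- sort(unique(as.integer(modules)))
  if (anyNA(modules) || any(modules < 0L | modules > 8L)) {
    stop("modules must be integers in 0..8")
  }
  if (!(stimulus %in% names(stimulus_library(horizon)))) {
    stop("unknown stimulus '", stimulus, "'; see stimulus_library()")
  }
  stopifnot(dose > 0, partner_dose >= 0, horizon > 0, h > 0, tol >= 0,
            crosstalk_scale > 0, all(scale_grid > 0))
  structure(
    list(modules = modules,
         anchor_target = names(SPECIES)[species_index(anchor_target)],
         partner_targets = names(SPECIES)[species_index(partner_targets)],
         dose = dose, partner_dose = partner_dose,
         stimulus = stimulus, horizon = horizon, h = h,
         crosstalk_scale = crosstalk_scale, scale_grid = scale_grid,
         tol = tol, inhibition = inhibition),
    class = "screen_config"
  )
}

# Shared simulation harness: memoised integrated outputs per
# (module, scale, stimulus pair, regimen label) within one screen run.
.io_cache <- function(cfg, params) {
  lib <- stimulus_library(cfg$horizon)
  cache <- new.env(parent = emptyenv())
  function(module_id, regimen, scale = cfg$crosstalk_scale,
           stim_names = c(cfg$stimulus, cfg$stimulus)) {
    key <- paste(module_id, format(scale, digits = 15),
                 paste(stim_names, collapse = "/"),
                 regimen_label(regimen),
                 paste(regimen$entries$dose, collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    stim <- list(G1 = lib[[stim_names[1L]]]$G1, G2 = lib[[stim_names[2L]]]$G2)
    traj <- tryCatch(
      simulate_module(build_module(module_id, scale, params), params, stim,
                      regimen, horizon = cfg$horizon, h = cfg$h,
                      inhibition = cfg$inhibition),
      error = function(e) stop("simulation of module ", module_id,
                               " (regimen ", regimen_label(regimen),
                               ", scale ", scale, ") failed: ",
                               conditionMessage(e))
    )
    cache[[key]] <- integrated_output(traj, cfg$horizon)
    cache[[key]]
  }
}

.as_screen_result <- function(df, kind, cfg) {
  rownames(df) <- NULL
  structure(df, class = c("screen_result", "data.frame"),
            kind = kind, config = cfg)
}

#' Single-drug efficacy screen across module topologies
#'
#' For each requested module, simulates the untreated and anchor-drug
#' trajectories under the configured stimulus, integrates the output and
#' scores the relative drug efficacy against the crosstalk-free module 0.
#' Negative efficacy marks crosstalk-mediated drug resistance.
#'
#' @param cfg A `screen_config`.
#' @param params Kinetic parameters.
#' @return A `screen_result` data frame with one row per module: columns
#'   `module_id`, `regimen`, `crosstalk_scale`, `stimulus`, `io_no_drug`,
#'   `io_drug`, `rde`.
#' @export
#' @examples
#' \donttest{
#' res <- single_drug_screen(screen_config(h = 0.05))
#' res[res$rde < 0, "module_id"]  # the drug-resistant topologies
#' }
single_drug_screen <- function(cfg = screen_config(),
                               params = default_parameters()) {
  io <- .io_cache(cfg, params)
  .single_screen_rows(cfg, io, cfg$crosstalk_scale,
                      c(cfg$stimulus, cfg$stimulus)) |>
    .as_screen_result("single_drug", cfg)
}

# One pass of the single-drug screen at a fixed scale and stimulus pair.
.single_screen_rows <- function(cfg, io, scale, stim_names) {
  untreated <- drug_regimen()
  anchor <- drug_regimen(cfg$anchor_target, cfg$dose)
  modules <- sort(unique(c(0L, cfg$modules)))
  base <- c(io(0L, untreated, scale, stim_names),
            io(0L, anchor, scale, stim_names))
  rows <- lapply(modules, function(m) {
    iom <- c(io(m, untreated, scale, stim_names),
             io(m, anchor, scale, stim_names))
    data.frame(module_id = m,
               regimen = regimen_label(anchor),
               crosstalk_scale = scale,
               stimulus = paste(stim_names, collapse = "/"),
               io_no_drug = iom[1L], io_drug = iom[2L],
               rde = relative_drug_efficacy(iom, base))
  })
  do.call(rbind, rows)
}

#' Pairwise drug-combination screen
#'
#' For each module and each partner target, simulates four arms (untreated,
#' anchor alone, partner alone, anchor + partner) and scores (i) the
#' relative efficacy of the combination against module 0 under the same
#' combination, (ii) the Bliss combination index with its
#' synergy/additivity/antagonism label, and (iii) whether the combination
#' increases or decreases the relative efficacy compared to the single
#' anchor drug.
#'
#' @inheritParams single_drug_screen
#' @return A `screen_result` with one row per (module, partner): columns
#'   `module_id`, `anchor`, `partner`, `regimen`, `crosstalk_scale`,
#'   `stimulus`, `io_no_drug`, `io_anchor`, `io_partner`, `io_combo`,
#'   `rde_single`, `rde_combo`, `r1`, `r2`, `r12`, `ci`, `label`,
#'   `direction`.
#' @export
combination_screen <- function(cfg = screen_config(),
                               params = default_parameters()) {
  io <- .io_cache(cfg, params)
  untreated <- drug_regimen()
  anchor <- drug_regimen(cfg$anchor_target, cfg$dose)
  modules <- sort(unique(c(0L, cfg$modules)))

  arm <- function(m, reg) io(m, reg)
  base_none <- arm(0L, untreated)
  base_anchor <- arm(0L, anchor)

  rows <- list()
  for (m in modules) {
    io_none <- arm(m, untreated)
    io_anchor <- arm(m, anchor)
    rde_single <- relative_drug_efficacy(c(io_none, io_anchor),
                                         c(base_none, base_anchor))
    for (px in cfg$partner_targets) {
      partner <- drug_regimen(px, cfg$partner_dose)
      combo <- drug_regimen(c(cfg$anchor_target, px),
                            c(cfg$dose, cfg$partner_dose))
      io_partner <- arm(m, partner)
      io_combo <- arm(m, combo)
      base_combo <- arm(0L, combo)
      rde_combo <- relative_drug_efficacy(c(io_none, io_combo),
                                          c(base_none, base_combo))
      bl <- bliss_combination_index(io_none, io_anchor, io_partner, io_combo)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m,
        anchor = cfg$anchor_target,
        partner = px,
        regimen = regimen_label(combo),
        crosstalk_scale = cfg$crosstalk_scale,
        stimulus = paste(cfg$stimulus, cfg$stimulus, sep = "/"),
        io_no_drug = io_none, io_anchor = io_anchor,
        io_partner = io_partner, io_combo = io_combo,
        rde_single = rde_single, rde_combo = rde_combo,
        r1 = bl$R1, r2 = bl$R2, r12 = bl$R12, ci = bl$CI,
        label = classify_synergy(bl$CI, cfg$tol),
        direction = compare_combo_to_single(rde_combo, rde_single)
      )
    }
  }
  .as_screen_result(do.call(rbind, rows), "combination", cfg)
}

#' Crosstalk-strength scan
#'
#' Repeats the single-drug screen at every crosstalk scale in
#' `cfg$scale_grid` and summarises, per module, the efficacy at the grid
#' endpoints and whether its sign switches (resistant -> sensitive or
#' sensitive -> resistant) as the crosstalk strengthens.
#'
#' @inheritParams single_drug_screen
#' @return A `screen_result` with one row per (module, scale), plus a
#'   `switching` attribute: a data frame with `module_id`, `rde_min_scale`,
#'   `rde_max_scale` and `switch` (`"to_sensitive"`, `"to_resistant"` or
#'   `"none"`).
#' @export
strength_scan <- function(cfg = screen_config(),
                          params = default_parameters()) {
  io <- .io_cache(cfg, params)
  stim <- c(cfg$stimulus, cfg$stimulus)
  grid <- sort(cfg$scale_grid)
  res <- do.call(rbind, lapply(grid, function(s)
    .single_screen_rows(cfg, io, s, stim)))
  lo <- res[res$crosstalk_scale == grid[1L], ]
  hi <- res[res$crosstalk_scale == grid[length(grid)], ]
  sw <- data.frame(
    module_id = lo$module_id,
    rde_min_scale = lo$rde,
    rde_max_scale = hi$rde[match(lo$module_id, hi$module_id)]
  )
  sw$switch <- ifelse(sw$rde_min_scale < 0 & sw$rde_max_scale > 0,
                      "to_sensitive",
                      ifelse(sw$rde_min_scale > 0 & sw$rde_max_scale < 0,
                             "to_resistant", "none"))
  out <- .as_screen_result(res, "strength_scan", cfg)
  attr(out, "switching") <- sw
  out
}

#' Stimulus-variation scan
#'
#' Repeats the single-drug screen across a set of stimulus conditions: each
#' named variant is applied to G1 alone (G2 kept at the basic S0), to G2
#' alone, and to both channels. The summary flags modules whose relative
#' efficacy is negative under a majority of conditions as prone to
#' resisting the anchor drug.
#'
#' @inheritParams single_drug_screen
#' @param stimuli Character vector of stimulus names from
#'   [stimulus_library()].
#' @return A `screen_result` with one row per (module, condition), plus a
#'   `majority_resistant` attribute: the module ids with `rde < 0` in more
#'   than half the conditions.
#' @export
stimulus_scan <- function(cfg = screen_config(),
                          stimuli = paste0("S", 1:6),
                          params = default_parameters()) {
  if (length(stimuli) == 0L) stop("at least one stimulus name is required")
  lib_names <- names(stimulus_library(cfg$horizon))
  unknown <- setdiff(stimuli, lib_names)
  if (length(unknown)) {
    stop("unknown stimulus name(s): ", paste(unknown, collapse = ", "))
  }
  conds <- unique(do.call(rbind, lapply(stimuli, function(s)
    rbind(c(s, s), c(s, "S0"), c("S0", s)))))
  io <- .io_cache(cfg, params)
  res <- do.call(rbind, lapply(seq_len(nrow(conds)), function(r)
    .single_screen_rows(cfg, io, cfg$crosstalk_scale, conds[r, ])))
  frac_neg <- tapply(res$rde < 0, res$module_id, mean)
  out <- .as_screen_result(res, "stimulus_scan", cfg)
  attr(out, "majority_resistant") <-
    as.integer(names(frac_neg)[frac_neg > 0.5])
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result: %s, %d rows>\n", attr(x, "kind"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Plot a screen result
#'
#' Bar chart of relative efficacy per module for single-drug screens, a
#' scale-response curve per module for strength scans, and a label heatmap
#' for combination screens. Requires ggplot2.
#'
#' @param result A `screen_result`.
#' @return A ggplot object.
#' @export
plot_screen_result <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_screen_result requires the ggplot2 package")
  }
  kind <- attr(result, "kind")
  df <- as.data.frame(result)
  df$module <- factor(paste0("M", df$module_id),
                      levels = paste0("M", 0:8))
  if (kind == "combination") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$partner, y = .data$module,
                                     fill = .data$label)) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::scale_fill_manual(values = c(synergy = "white",
                                            additivity = "grey70",
                                            antagonism = "black")) +
      ggplot2::labs(x = "partner target", y = NULL, fill = NULL)
  } else if (kind == "strength_scan") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$crosstalk_scale,
                                     y = .data$rde,
                                     colour = .data$module)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "crosstalk scale", y = "relative drug efficacy")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$rde)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::labs(x = NULL, y = "relative drug efficacy")
  }
}
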