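#' Species roles of the two-pathway scaffold
#'
#' The model tracks five species: the receptors/upstream proteins A and C
#' (activated by growth factors G1 and G2), the downstream effectors B and D,
#' and the common signaling output O. Indices 1--5 map to A, B, C, D, O.
#'
#' @format Named integer vector of length five.
#' @export
SPECIES <- c(A = 1L, B = 2L, C = 3L, D = 4L, O = 5L)

#' Resolve a species name or index to its integer index
#'
#' @param species A species given as one of `"A"`, `"B"`, `"C"`, `"D"`, `"O"`
#'   or as an integer in 1..5. Vectorised.
#' @return Integer vector of species indices.
#' @export
#' @examples
#' species_index(c("B", "D"))
species_index <- function(species) {
  if (is.character(species)) {
    idx <- SPECIES[toupper(species)]
    if (anyNA(idx)) {
      stop("unknown species name(s): ",
           paste(species[is.na(idx)], collapse = ", "),
           "; expected A, B, C, D or O")
    }
    return(unname(idx))
  }
  idx <- as.integer(species)
  if (anyNA(idx) || any(idx < 1L | idx > 5L)) {
    stop("species index must be an integer in 1..5 (A, B, C, D, O)")
  }
  idx
}

#' Standard kinetic parameters
#'
#' Returns the standard non-dimensional parameter set: per-species degradation
#' rates d_i, the input-function constants for the two growth-factor channels
#' (V_A, K_A for G1 -> A and V_C, K_C for G2 -> C), the per-species drug
#' Michaelis constants K_D, and the default edge kinetics (maximal rate +0.4
#' for activation, -1 for inhibition, Michaelis constant 0.8).
#'
#' @return An object of class `kinetic_parameters`: a list with elements
#'   `d` (length 5), `V_A`, `K_A`, `V_C`, `K_C`, `K_D` (length 5),
#'   `V_act`, `V_inh`, `K_default`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$d
default_parameters <- function() {
  structure(
    list(
      d = rep(0.2, 5L),
      V_A = 0.2, K_A = 0.5,
      V_C = 0.2, K_C = 0.5,
      K_D = rep(0.1, 5L),
      V_act = 0.4, V_inh = -1, K_default = 0.8
    ),
    class = "kinetic_parameters"
  )
}

# Crosstalk edge table per registered module: from/to species indices, sign
# (+1 activation, -1 inhibition), and a magnitude weight relative to the
# default rate for that sign. Module 6's mutual inhibition is asymmetric:
# D -| A at full strength, B -| C weaker (weight set by `m6_weak_ratio`).
.module_crosstalk <- function(module_id, m6_weak_ratio = 0.5) {
  edge <- function(from, to, sign, weight = 1) {
    data.frame(from = species_index(from), to = species_index(to),
               sign = sign, weight = weight)
  }
  switch(as.character(module_id),
    "0" = edge(character(0), character(0), numeric(0), numeric(0)),
    "1" = edge("A", "D", +1),
    "2" = edge("A", "D", -1),
    "3" = edge("B", "C", +1),
    "4" = edge("B", "C", -1),
    "5" = rbind(edge("B", "C", +1), edge("D", "A", +1)),
    "6" = rbind(edge("B", "C", -1, m6_weak_ratio), edge("D", "A", -1)),
    "7" = rbind(edge("B", "C", -1), edge("D", "A", +1)),
    "8" = rbind(edge("B", "C", +1), edge("D", "A", -1)),
    stop("unknown module id '", module_id, "': valid ids are 0..8")
  )
}

#' Build one of the nine registered module topologies
#'
#' All modules share the four backbone activations A -> B, B -> O, C -> D and
#' D -> O. Modules 1--8 add one or two crosstalk links between the pathways:
#' M1 A -> D, M2 A -| D, M3 B -> C, M4 B -| C, M5 B -> C and D -> A,
#' M6 B -| C and D -| A (mutual inhibition, with D -| A the stronger link),
#' M7 B -| C and D -> A, M8 B -> C and D -| A. Module 0 has no crosstalk and
#' serves as the comparison baseline for drug-efficacy scoring.
#'
#' @param module_id Integer 0..8.
#' @param crosstalk_scale Positive multiplier applied to the magnitude of the
#'   crosstalk rates only (backbone rates are never rescaled). Scale 10
#'   corresponds to ten-fold crosstalk strength.
#' @param params A `kinetic_parameters` object supplying the default edge
#'   rates and Michaelis constant.
#' @param m6_weak_ratio Magnitude of module 6's B -| C inhibition relative to
#'   its full-strength D -| A inhibition; must lie in (0, 1].
#' @return An object of class `module_topology`: a list with the 5x5 maximal
#'   rate matrix `V` (row = source, column = target), the 5x5 Michaelis
#'   constant matrix `K`, the crosstalk edge index matrix `crosstalk_edges`
#'   (columns `from`, `to`), `module_id` and `crosstalk_scale`.
#' @export
#' @examples
#' m1 <- build_module(1)
#' m1$V[SPECIES["A"], SPECIES["D"]]  # the A -> D crosstalk activation
build_module <- function(module_id, crosstalk_scale = 1,
                         params = default_parameters(),
                         m6_weak_ratio = 0.5) {
  if (length(module_id) != 1L || is.na(suppressWarnings(as.integer(module_id))) ||
      as.integer(module_id) != as.numeric(module_id)) {
    stop("module_id must be a single integer in 0..8")
  }
  module_id <- as.integer(module_id)
  if (module_id < 0L || module_id > 8L) {
    stop("unknown module id '", module_id, "': valid ids are 0..8")
  }
  stopifnot(is.numeric(crosstalk_scale), length(crosstalk_scale) == 1L,
            crosstalk_scale > 0)
  stopifnot(m6_weak_ratio > 0, m6_weak_ratio <= 1)

  V <- matrix(0, 5L, 5L, dimnames = list(names(SPECIES), names(SPECIES)))
  K <- matrix(0, 5L, 5L, dimnames = dimnames(V))
  backbone <- cbind(from = c(1L, 2L, 3L, 4L), to = c(2L, 5L, 4L, 5L))
  V[backbone] <- params$V_act
  K[backbone] <- params$K_default

  ct <- .module_crosstalk(module_id, m6_weak_ratio)
  if (nrow(ct)) {
    ij <- cbind(ct$from, ct$to)
    V[ij] <- ifelse(ct$sign > 0, params$V_act, params$V_inh) *
      ct$weight * crosstalk_scale
    K[ij] <- params$K_default
  }

  structure(
    list(
      module_id = module_id,
      V = V, K = K,
      crosstalk_edges = cbind(from = ct$from, to = ct$to),
      crosstalk_scale = crosstalk_scale
    ),
    class = "module_topology"
  )
}

#' Construct a custom module topology
#'
#' @param V 5x5 numeric matrix of maximal rates (row = source, column =
#'   target); positive entries are activations, negative entries inhibitions.
#' @param K 5x5 numeric matrix of Michaelis constants, positive wherever the
#'   matching `V` entry is nonzero.
#' @param crosstalk_edges Two-column integer matrix (`from`, `to`) flagging
#'   which nonzero `V` entries are crosstalk links rather than backbone links.
#' @param module_id Identifier stored in the result; `"custom"` by default.
#' @param crosstalk_scale Scale already applied to the crosstalk entries
#'   (recorded for provenance only).
#' @return A `module_topology` object.
#' @seealso [validate_topology()] to check the structural invariants.
#' @export
module_topology <- function(V, K, crosstalk_edges = NULL,
                            module_id = "custom", crosstalk_scale = 1) {
  stopifnot(is.matrix(V), all(dim(V) == c(5L, 5L)),
            is.matrix(K), all(dim(K) == c(5L, 5L)))
  dimnames(V) <- dimnames(K) <- list(names(SPECIES), names(SPECIES))
  if (is.null(crosstalk_edges)) {
    crosstalk_edges <- cbind(from = integer(0), to = integer(0))
  }
  structure(
    list(module_id = module_id, V = V, K = K,
         crosstalk_edges = crosstalk_edges,
         crosstalk_scale = crosstalk_scale),
    class = "module_topology"
  )
}

#' Check a topology against the structural invariants
#'
#' Verifies that all four backbone activations are present, that every
#' nonzero rate has a positive Michaelis constant, and that the crosstalk
#' edge annotations point at nonzero rates. Validation never throws; it
#' reports problems as text.
#'
#' @param topology A `module_topology`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
#' @examples
#' validate_topology(build_module(3))  # character(0)
validate_topology <- function(topology) {
  out <- character(0)
  V <- topology$V
  K <- topology$K
  if (!is.matrix(V) || !all(dim(V) == c(5L, 5L)) ||
      !is.matrix(K) || !all(dim(K) == c(5L, 5L))) {
    return("V and K must both be 5x5 matrices")
  }
  backbone <- cbind(c(1L, 2L, 3L, 4L), c(2L, 5L, 4L, 5L))
  lab <- function(i, j) paste0(names(SPECIES)[i], "->", names(SPECIES)[j])
  for (r in seq_len(nrow(backbone))) {
    i <- backbone[r, 1L]; j <- backbone[r, 2L]
    if (V[i, j] <= 0) {
      out <- c(out, paste0("missing backbone activation ", lab(i, j),
                           " (V[", i, ",", j, "] = ", V[i, j], ")"))
    }
  }
  bad_k <- which(V != 0 & K <= 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bad_k))) {
    i <- bad_k[r, 1L]; j <- bad_k[r, 2L]
    out <- c(out, paste0("K[", i, ",", j, "] must be > 0 where V[", i, ",", j,
                         "] = ", V[i, j], " is nonzero"))
  }
  ce <- topology$crosstalk_edges
  for (r in seq_len(NROW(ce))) {
    i <- ce[r, 1L]; j <- ce[r, 2L]
    if (V[i, j] == 0) {
      out <- c(out, paste0("crosstalk edge ", lab(i, j),
                           " annotated but V[", i, ",", j, "] is zero"))
    }
  }
  out
}

#' Construct a piecewise-constant stimulus profile
#'
#' A stimulus profile describes the time course of one growth-factor channel
#' (G1 or G2) as an ordered set of non-overlapping constant segments; outside
#' every segment the stimulus is zero. Segments are half-open intervals
#' `[t_start, t_end)`.
#'
#' @param name Profile label.
#' @param channel `"G1"` or `"G2"`.
#' @param segments Data frame with columns `t_start`, `t_end`, `amplitude`
#'   (amplitudes in `[0, 1]` under the standard, normalised stimuli).
#' @return An object of class `stimulus_profile`.
#' @export
stimulus_profile <- function(name, channel, segments) {
  stopifnot(channel %in% c("G1", "G2"),
            is.data.frame(segments),
            all(c("t_start", "t_end", "amplitude") %in% names(segments)))
  segments <- segments[order(segments$t_start), , drop = FALSE]
  if (any(segments$amplitude < 0)) stop("stimulus amplitudes must be >= 0")
  if (any(segments$t_end <= segments$t_start)) {
    stop("every stimulus segment needs t_end > t_start")
  }
  if (nrow(segments) > 1L &&
      any(segments$t_start[-1L] < segments$t_end[-nrow(segments)])) {
    stop("stimulus segments must not overlap")
  }
  structure(list(name = name, channel = channel, segments = segments),
            class = "stimulus_profile")
}

#' Evaluate a stimulus profile
#'
#' @param profile A `stimulus_profile`.
#' @param t Numeric vector of times.
#' @return Amplitude of the segment covering each `t` (zero outside all
#'   segments).
#' @export
#' @examples
#' s0 <- stimulus_library()[["S0"]]$G1
#' stimulus_value(s0, c(10, 50))
stimulus_value <- function(profile, t) {
  seg <- profile$segments
  vapply(t, function(ti) {
    hit <- ti >= seg$t_start & ti < seg$t_end
    if (any(hit)) seg$amplitude[which(hit)[1L]] else 0
  }, numeric(1))
}

.seg <- function(t_start, t_end, amplitude) {
  data.frame(t_start = t_start, t_end = t_end, amplitude = amplitude)
}

#' The built-in stimulus library (S0 and six variants)
#'
#' S0 is the basic stimulus: a unit rectangular pulse on t in [0, 30) applied
#' to both channels. The six variants probe robustness of the screen
#' conclusions to the input shape: S1 sustained unit step over the full
#' horizon, S2 short pulse (t in [0, 10)), S3 double pulse ([0, 15) and
#' [40, 55)), S4 rising staircase ramp to 1 over [0, 30), S5 half-amplitude
#' pulse, S6 delayed pulse ([20, 50)).
#'
#' @param horizon Horizon used to terminate the sustained step S1.
#' @return Named list; each element is a list with `G1` and `G2`
#'   `stimulus_profile` objects of the same shape.
#' @export
stimulus_library <- function(horizon = 100) {
  shapes <- list(
    S0 = .seg(0, 30, 1),
    S1 = .seg(0, horizon, 1),
    S2 = .seg(0, 10, 1),
    S3 = .seg(c(0, 40), c(15, 55), c(1, 1)),
    S4 = .seg(seq(0, 25, by = 5), seq(5, 30, by = 5), seq_len(6) / 6),
    S5 = .seg(0, 30, 0.5),
    S6 = .seg(20, 50, 1)
  )
  lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
    list(G1 = stimulus_profile(nm, "G1", shapes[[nm]]),
         G2 = stimulus_profile(nm, "G2", shapes[[nm]]))
  })
}

#' Construct a drug regimen
#'
#' A regimen is a set of dosing entries, each naming a target species, a
#' constant dose applied from an onset time, and that onset time. An empty
#' regimen is the untreated condition. Two entries may share a target; their
#' doses add inside the drug factor, so "B combined with B" doubles the
#' effective dose on B.
#'
#' @param targets Species names or indices, one per entry (empty for no
#'   treatment).
#' @param doses Nonnegative doses, recycled to the number of targets
#'   (default 1).
#' @param t_on Onset times, recycled (default 0: treated for the whole run).
#' @return An object of class `drug_regimen` with a data frame `entries`
#'   (`target`, `dose`, `t_on`).
#' @export
#' @examples
#' drug_regimen("B")                 # single B-targeting drug, dose 1
#' drug_regimen(c("B", "D"))         # combination of B- and D-targeting drugs
#' drug_regimen()                    # untreated
drug_regimen <- function(targets = character(0), doses = 1, t_on = 0) {
  if (length(targets) == 0L) {
    entries <- data.frame(target = integer(0), dose = numeric(0),
                          t_on = numeric(0))
  } else {
    idx <- species_index(targets)
    doses <- rep_len(doses, length(idx))
    t_on <- rep_len(t_on, length(idx))
    if (any(doses < 0)) stop("drug doses must be >= 0")
    entries <- data.frame(target = idx, dose = doses, t_on = t_on)
  }
  structure(list(entries = entries), class = "drug_regimen")
}

#' Human-readable label for a regimen
#'
#' @param regimen A `drug_regimen`.
#' @return A label such as `"none"`, `"B"` or `"B+D"`.
#' @export
regimen_label <- function(regimen) {
  e <- regimen$entries
  if (nrow(e) == 0L) return("none")
  paste(names(SPECIES)[e$target], collapse = "+")
}

#' @export
print.module_topology <- function(x, ...) {
  cat("Signaling module", x$module_id,
      sprintf("(crosstalk scale %g)\n", x$crosstalk_scale))
  ce <- x$crosstalk_edges
  if (NROW(ce) == 0L) {
    cat("  no crosstalk (baseline two-pathway scaffold)\n")
  } else {
    for (r in seq_len(nrow(ce))) {
      v <- x$V[ce[r, 1L], ce[r, 2L]]
      cat(sprintf("  crosstalk %s %s %s (V = %g)\n",
                  names(SPECIES)[ce[r, 1L]],
                  if (v > 0) "->" else "-|",
                  names(SPECIES)[ce[r, 2L]], v))
    }
  }
  invisible(x)
}

#' @export
print.drug_regimen <- function(x, ...) {
  cat("Drug regimen:", regimen_label(x), "\n")
  if (nrow(x$entries)) print(x$entries)
  invisible(x)
}
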