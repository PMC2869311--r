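#' Effective protein activity of each module
#'
#' A module's proteins act on the epigenome in proportion to their
#' average expression level, but only if that level exceeds the minimal
#' activity threshold `a`; below it the activity is zero.
#'
#' @param gen_avg Numeric vector of average expression levels in
#'   `[0, 1]` (one per module).
#' @param params A [model_parameters()] object.
#' @return Numeric vector of activities in `[0, 1]`.
#' @export
protein_activity <- function(gen_avg, params) {
  ifelse(gen_avg > params$a, gen_avg, 0)
}

#' External cue acting on one module's chromatin during telophase
#'
#' Signalling products and culture conditions are modelled as additive
#' single-site fields in the telophase Hamiltonian, acting like rule 1:
#' an `"open"` cue lowers the energy of the +1 (open) state, a
#' `"silence"` cue lowers the -1 state, a `"bivalent"` cue penalises
#' |S| and so favours the bivalent state. Strength is expressed in
#' units of `G`.
#'
#' @param target 0-based module id the cue acts on.
#' @param strength Non-negative multiplier of `G`.
#' @param type One of `"open"`, `"silence"`, `"bivalent"`.
#' @return An object of class `cue_spec`.
#' @export
cue_spec <- function(target, strength = 1, type = c("open", "silence",
                                                    "bivalent")) {
  type <- match.arg(type)
  if (length(strength) != 1L || !is.finite(strength) || strength < 0)
    stop("cue strength must be a single non-negative number")
  structure(list(target = as.integer(target), strength = strength,
                 type = type), class = "cue_spec")
}

#' Single-site fields of the telophase (epigenetic) Hamiltonian
#'
#' With the protein environment held fixed, the telophase Hamiltonian
#' is a sum of independent single-site terms
#' `E(S) = sum_i h_i S_i + c_i |S_i|`. Writing `p_j` for the protein
#' activity of module j, the four rules contribute:
#'
#' * rule 1 (self-maintenance): `-G p_i` to `h_i`;
#' * rule 2 (silence the progenitor and sibling): `+G p_j` to `h_i` for
#'   every j having i as parent or sibling;
#' * rule 3 (bivalence on immediate progeny): `+G p_parent(i)` to `c_i`;
#' * rule 4 (long-range methylation): `+H p_j` to `h_i` for every j
#'   with i in its distal set (all non-self, non-descendant modules).
#'
#' With `lif_absent = TRUE`, the rule 3 action of the root module on
#' its children is replaced by a rule 1-like positive field `-G p_root`
#' (ES culture medium withdrawn: the ES module opens its progeny's
#' chromatin, enabling self-initiated differentiation). With
#' `rule4_range = "nearest"` the methylation field is restricted to the
#' parent and sibling — the ablation that destroys the long-range
#' constraint.
#'
#' @param protein_env Numeric vector of per-module average expression.
#' @param topology A [build_hierarchy()] object.
#' @param params A [model_parameters()] object.
#' @param cues Optional list of [cue_spec()] objects.
#' @param lif_absent Logical; ES-medium-absent rule variant.
#' @param rule4_range `"distal"` (default) or `"nearest"`.
#' @return List with numeric vectors `h` and `c`.
#' @export
telophase_fields <- function(protein_env, topology, params, cues = NULL,
                             lif_absent = FALSE,
                             rule4_range = c("distal", "nearest")) {
  rule4_range <- match.arg(rule4_range)
  n <- topology$n_nodes
  if (length(protein_env) != n)
    stop("protein_env must have one entry per module")
  p <- protein_activity(protein_env, params)
  G <- params$G; H <- params$H

  h <- -G * p                      # rule 1
  cc <- numeric(n)
  ptot <- sum(p)
  for (i in 0:(n - 1L)) {
    k <- i + 1L
    # rule 2: modules whose parent or sibling is i
    src <- c(children_of(topology, i), sibling_of(topology, i))
    src <- src[!is.na(src)]
    h[k] <- h[k] + G * sum(p[src + 1L])
    # rule 4
    if (rule4_range == "distal") {
      anc <- ancestors_of(topology, i)
      h[k] <- h[k] + H * (ptot - p[k] - sum(p[anc + 1L]))
    } else {
      h[k] <- h[k] + H * sum(p[src + 1L])
    }
    # rule 3: bivalence from the parent's proteins
    par <- parent_of(topology, i)
    if (!is.na(par)) {
      if (lif_absent && par == 0L) {
        h[k] <- h[k] - G * p[par + 1L]   # rule 1-like opening instead
      } else {
        cc[k] <- cc[k] + G * p[par + 1L]
      }
    }
  }

  for (cue in cues) {
    stopifnot(inherits(cue, "cue_spec"))
    k <- .check_node(topology, cue$target) + 1L
    s <- cue$strength * G
    if (cue$type == "open") h[k] <- h[k] - s
    else if (cue$type == "silence") h[k] <- h[k] + s
    else cc[k] <- cc[k] + s
  }

  list(h = h, c = cc)
}

#' Telophase (epigenetic) Hamiltonian
#'
#' Energy of an epigenetic spin configuration under a fixed protein
#' environment; the sum of the four rule terms described in
#' [telophase_fields()]. Zero protein activity and no cues give
#' identically zero energy.
#'
#' @param ep Integer vector of epigenetic spins in `{-1, 0, +1}`.
#' @inheritParams telophase_fields
#' @return A single dimensionless energy.
#' @examples
#' topo <- build_hierarchy(2)
#' pars <- model_parameters()
#' telophase_energy(c(-1, 1, -1), c(0, 1, 0), topo, pars)  # -155
#' @export
telophase_energy <- function(ep, protein_env, topology, params,
                             cues = NULL, lif_absent = FALSE,
                             rule4_range = "distal") {
  if (length(ep) != topology$n_nodes)
    stop("ep must have one spin per module")
  if (!all(ep %in% c(-1, 0, 1))) stop("ep spins must be in {-1, 0, +1}")
  fl <- telophase_fields(protein_env, topology, params, cues = cues,
                         lif_absent = lif_absent,
                         rule4_range = rule4_range)
  sum(fl$h * ep + fl$c * abs(ep))
}

#' Nearest-neighbour module pairs carrying mutual repression
#'
#' All parent-child edges plus all sibling pairs, each listed once.
#'
#' @inheritParams parent_of
#' @return Two-column integer matrix of 0-based module ids (0 rows for
#'   the single-module tree).
#' @export
neighbor_pairs <- function(topology) {
  n <- topology$n_nodes
  if (n == 1L) return(matrix(integer(0), ncol = 2L))
  ids <- 1:(n - 1L)
  edges <- cbind(topology$parent[ids + 1L], ids)
  sib <- cbind(ids[ids %% 2L == 1L], ids[ids %% 2L == 1L] + 1L)
  out <- rbind(edges, sib)
  storage.mode(out) <- "integer"
  out
}

#' Interphase (expression) Hamiltonian
#'
#' Energy of a binary expression configuration under a fixed epigenome:
#' `E = -F sum_i (<S_i^ep> - b) S_i + J sum_(i,j) S_i S_j` over
#' nearest-neighbour module pairs. The first term (rule 1') favours
#' expression exactly when the epigenetic availability exceeds `b`, and
#' represses heterochromatin (`<S^ep> = -1`) more strongly than
#' bivalent chromatin (`<S^ep> = 0`). The second (rule 2') is the
#' mutual repression between directly competing modules.
#'
#' @param gen Integer vector of expression spins in `{0, 1}`.
#' @param ep_env Numeric vector of per-module average epigenetic state
#'   in `[-1, 1]`.
#' @inheritParams telophase_fields
#' @return A single dimensionless energy.
#' @export
interphase_energy <- function(gen, ep_env, topology, params) {
  n <- topology$n_nodes
  if (length(gen) != n) stop("gen must have one spin per module")
  if (length(ep_env) != n) stop("ep_env must have one entry per module")
  if (!all(gen %in% c(0, 1))) stop("gen spins must be in {0, 1}")
  f <- -params$F * (ep_env - params$b)
  e <- sum(f * gen)
  prs <- neighbor_pairs(topology)
  if (nrow(prs) > 0L)
    e <- e + params$J * sum(gen[prs[, 1L] + 1L] * gen[prs[, 2L] + 1L])
  e
}
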