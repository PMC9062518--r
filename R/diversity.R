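# Alpha, beta, and gamma diversity labels from vegetation plots.
#
# For every focal plot: alpha is the focal species richness; the
# neighbourhood is the N nearest other plots (Euclidean distance in
# equal-area projected metres, ties broken by ascending plot id); gamma is
# the pooled richness of focal + neighbours; beta is the multiple-site
# Sorensen dissimilarity over that neighbourhood, with site pairs formed
# between each neighbour i and the focal site j = N + 1:
#
#   beta_sor = (A + B) / (2 * (sum_i S_i - S_T) + A + B)
#   A = sum_i min(b_ij, b_ji),  B = sum_i max(b_ij, b_ji)
#
# where b_ij / b_ji count species present only in site i / only in the
# focal site within each pair, S_i is the richness of site i (the sum runs
# over all N + 1 sites including the focal), and S_T is the union richness
# of all sites. With a single neighbour this reduces exactly to the
# classical pairwise Sorensen dissimilarity.

#' Alpha diversity of a plot
#'
#' Species richness: the number of distinct (normalized) species names.
#'
#' @param species character vector of species names (duplicates allowed;
#'   they count once).
#' @return integer richness.
#' @export
#' @examples
#' alpha_diversity(c("a sp1", "b sp2", "a sp1"))  # 2
alpha_diversity <- function(species) {
  length(unique(normalize_names(species)))
}

#' Gamma diversity of a focal plot and its neighbours
#'
#' Richness of the union of species sets over the focal plot and all
#' neighbouring plots.
#'
#' @param focal_species character vector: focal plot species.
#' @param neighbor_species list of character vectors, one per neighbour.
#' @return integer pooled richness.
#' @export
gamma_diversity <- function(focal_species, neighbor_species) {
  if (!length(neighbor_species)) {
    stop_divnn("gamma diversity requires at least one neighbour")
  }
  all_sp <- c(normalize_names(focal_species),
              unlist(lapply(neighbor_species, normalize_names)))
  length(unique(all_sp))
}

#' Multiple-site Sorensen dissimilarity of a neighbourhood
#'
#' Computes the multiple-site Sorensen dissimilarity between a focal plot
#' and its N neighbours. Pairs are formed between each neighbour and the
#' focal plot; `A` and `B` are the sums over pairs of the smaller and
#' larger one-sided unique-species counts, and the denominator uses the
#' total richness over all N + 1 sites (including the focal) minus the
#' union richness. The value lies in \[0, 1\]: 0 when every neighbour has
#' exactly the focal composition, 1 when all sites are mutually disjoint.
#'
#' @inheritParams gamma_diversity
#' @param terms if `TRUE`, return the intermediate terms
#'   (`A, B, sum_S, S_T`) as an attribute.
#' @return numeric dissimilarity in \[0, 1\].
#' @export
#' @examples
#' beta_sorensen(c("a", "b"), list(c("a", "c"), c("a", "d")))  # 0.5
beta_sorensen <- function(focal_species, neighbor_species, terms = FALSE) {
  if (!length(neighbor_species)) {
    stop_divnn("beta diversity requires at least one neighbour")
  }
  focal <- unique(normalize_names(focal_species))
  nb <- lapply(neighbor_species, function(s) unique(normalize_names(s)))
  sizes <- c(vapply(nb, length, integer(1)), length(focal))
  union_all <- unique(c(focal, unlist(nb)))
  if (!length(union_all)) {
    stop_divnn("beta_sorensen undefined: all sites are empty")
  }
  b_ij <- vapply(nb, function(s) sum(!(s %in% focal)), integer(1))
  b_ji <- vapply(nb, function(s) sum(!(focal %in% s)), integer(1))
  A <- sum(pmin(b_ij, b_ji))
  B <- sum(pmax(b_ij, b_ji))
  sum_S <- sum(sizes)
  S_T <- length(union_all)
  denom <- 2 * (sum_S - S_T) + A + B
  if (denom == 0) {
    stop_divnn("beta_sorensen undefined: denominator is zero")
  }
  out <- (A + B) / denom
  if (terms) {
    attr(out, "terms") <- c(A = A, B = B, sum_S = sum_S, S_T = S_T)
  }
  out
}

#' Find the N nearest neighbouring plots of a focal plot
#'
#' Euclidean distance in projected metres; the focal plot itself is never
#' a candidate. Ties at identical distance are broken by ascending plot
#' id, so results are deterministic. The returned radius is the distance
#' to the Nth nearest neighbour — the smallest focal-centred circle
#' encompassing all N neighbours.
#'
#' @param focal_id plot id of the focal plot (must occur in `plots`).
#' @param plots data.frame with columns `plot_id, x, y`.
#' @param n number of neighbours N.
#' @return list with `neighbor_ids` (character, ordered by distance) and
#'   `radius` (metres).
#' @export
find_neighbors <- function(focal_id, plots, n) {
  idx <- match(focal_id, plots$plot_id)
  if (is.na(idx)) stop_divnn("focal plot '%s' not found", focal_id)
  cand <- plots[-idx, , drop = FALSE]
  if (nrow(cand) < n) {
    stop_divnn("need %d neighbours but only %d other plots exist (short by %d)",
               n, nrow(cand), n - nrow(cand))
  }
  d <- sqrt((cand$x - plots$x[idx])^2 + (cand$y - plots$y[idx])^2)
  ord <- order(d, cand$plot_id)[seq_len(n)]
  list(neighbor_ids = cand$plot_id[ord], radius = d[ord[n]])
}

#' Compute diversity labels for every plot
#'
#' For each plot: alpha (focal richness), beta (multiple-site Sorensen
#' dissimilarity over the N nearest neighbours), gamma (pooled richness of
#' focal plus neighbours), and the neighbourhood radius (distance to the
#' Nth neighbour), which is itself used as a model feature carrying the
#' spatial scale of the gamma estimate.
#'
#' @param plots data.frame with columns `plot_id, x, y, area` and a list
#'   column `species`.
#' @param n neighbourhood size N (default 50, the operational choice for
#'   full-scale training data).
#' @return data.frame of class `diversity_labels`: one row per plot with
#'   `plot_id, alpha, beta, gamma, radius, n` and a list column
#'   `neighbor_ids`.
#' @export
label_sites <- function(plots, n = 50L) {
  stopifnot(is.data.frame(plots),
            all(c("plot_id", "x", "y", "species") %in% names(plots)))
  if (nrow(plots) < n + 1) {
    stop_divnn("need at least N + 1 = %d plots, have %d", n + 1, nrow(plots))
  }
  sp <- plots$species
  names(sp) <- plots$plot_id
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    nb <- find_neighbors(plots$plot_id[i], plots, n)
    nb_sp <- sp[nb$neighbor_ids]
    list(plot_id = plots$plot_id[i],
         alpha = alpha_diversity(sp[[i]]),
         beta = beta_sorensen(sp[[i]], nb_sp),
         gamma = gamma_diversity(sp[[i]], nb_sp),
         radius = nb$radius,
         neighbor_ids = nb$neighbor_ids)
  })
  out <- data.frame(
    plot_id = vapply(rows, `[[`, character(1), "plot_id"),
    alpha = vapply(rows, `[[`, integer(1), "alpha"),
    beta = vapply(rows, `[[`, numeric(1), "beta"),
    gamma = vapply(rows, `[[`, integer(1), "gamma"),
    radius = vapply(rows, `[[`, numeric(1), "radius"),
    n = as.integer(n)
  )
  out$neighbor_ids <- lapply(rows, `[[`, "neighbor_ids")
  class(out) <- c("diversity_labels", "data.frame")
  out
}

#' Write a diversity-labels table
#'
#' @param labels a [label_sites()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(
    data.frame(plot_id = labels$plot_id, alpha = labels$alpha,
               beta = labels$beta, gamma = labels$gamma,
               radius_m = labels$radius, N = labels$n),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a diversity-labels table
#'
#' @param path CSV written by [write_labels()].
#' @return data.frame with `plot_id, alpha, beta, gamma, radius, n`.
#' @export
read_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "alpha", "beta", "gamma", "radius_m", "N")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_divnn("labels file missing column(s): %s", paste(miss, collapse = ", "))
  }
  data.frame(plot_id = as.character(d$plot_id), alpha = d$alpha,
             beta = d$beta, gamma = d$gamma, radius = d$radius_m, n = d$N)
}
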