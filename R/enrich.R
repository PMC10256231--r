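#' Rank-based category test (Mann-Whitney U) on an ordered feature list
#'
#' For each category, tests whether its members sit higher or lower in a
#' ranked feature list than non-members, with a two-sided Mann-Whitney U
#' test (normal approximation with tie correction, members as group 1);
#' p-values are BH-adjusted across categories. Typical use: gene lists
#' ranked by decreasing Moran's I or normalized CV against functional
#' categories.
#'
#' @param ranked_ids Character vector of feature ids, best first.
#' @param categories Named list mapping category id to member feature ids;
#'   every member must appear in `ranked_ids`, and each category must have
#'   at least 2 members and fewer than `length(ranked_ids)`.
#' @return Data frame: category, n_members, U, p, q.
#' @export
ranked_category_mwu <- function(ranked_ids, categories) {
  stopifnot(is.character(ranked_ids), is.list(categories),
            length(categories) >= 1)
  n <- length(ranked_ids)
  rank_of <- stats::setNames(seq_len(n), ranked_ids)
  rows <- lapply(names(categories), function(cat) {
    members <- categories[[cat]]
    if (length(members) == 0) stop("empty category: ", cat)
    if (!all(members %in% ranked_ids))
      stop("category ", cat, " has members absent from the ranked list")
    if (length(members) < 2 || length(members) >= n)
      stop("category ", cat, " must have >= 2 and < n members")
    grp <- ranked_ids %in% members
    wt <- stats::wilcox.test(rank_of[grp], rank_of[!grp],
                             exact = FALSE, correct = TRUE)
    data.frame(category = cat, n_members = length(members),
               U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Hypergeometric category enrichment of a hit set
#'
#' Upper-tail hypergeometric test per category: the p-value is the
#' probability of an overlap at least as large as observed when drawing
#' `|hits|` features from the universe; BH-adjusted across categories.
#'
#' @param hit_set Character vector of hit feature ids (subset of universe).
#' @param categories Named list mapping category id to member ids; every
#'   member must be in `universe`.
#' @param universe Character vector of all testable feature ids.
#' @return Data frame: category, n_members, overlap, p, q.
#' @export
hypergeometric_enrichment <- function(hit_set, categories, universe) {
  stopifnot(all(hit_set %in% universe))
  n_u <- length(universe)
  n_h <- length(hit_set)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(categories[[cat]], universe)
    if (length(members) < length(categories[[cat]]))
      stop("category ", cat, " has members outside the universe")
    ov <- length(intersect(members, hit_set))
    p <- stats::phyper(ov - 1, length(members), n_u - length(members),
                       n_h, lower.tail = FALSE)
    data.frame(category = cat, n_members = length(members), overlap = ov,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
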