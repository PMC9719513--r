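#' catFISH per-animal activation counts
#'
#' Per animal: the number of counted Vgat+ cells, the number cytoplasmic
#' c-Fos-exon-positive (activated by the first stimulus), nuclear
#' intron-positive (second stimulus) and double-positive.
#'
#' @param animal_id animal identifiers.
#' @param group stimulus-order group: `"O-F"` (object then fox urine),
#'   `"F-O"`, or `"O-O"`.
#' @param n_vgat,n_exon,n_intron,n_both nonnegative integer counts with
#'   `n_both <= min(n_exon, n_intron)` and `n_exon, n_intron <= n_vgat`.
#' @return data frame of class `catfish_counts`.
#' @export
catfish_counts <- function(animal_id, group, n_vgat, n_exon, n_intron,
                           n_both) {
  d <- data.frame(animal_id = as.character(animal_id),
                  group = as.character(group),
                  n_vgat = as.integer(n_vgat), n_exon = as.integer(n_exon),
                  n_intron = as.integer(n_intron), n_both = as.integer(n_both),
                  stringsAsFactors = FALSE)
  if (!all(d$group %in% c("O-F", "F-O", "O-O")))
    stop("group must be one of O-F, F-O, O-O")
  with(d, {
    if (any(c(n_vgat, n_exon, n_intron, n_both) < 0))
      stop("counts must be nonnegative")
    if (any(n_both > pmin(n_exon, n_intron)))
      stop("n_both cannot exceed min(n_exon, n_intron)")
    if (any(n_exon > n_vgat) || any(n_intron > n_vgat))
      stop("marker counts cannot exceed n_vgat")
  })
  class(d) <- c("catfish_counts", "data.frame")
  d
}

#' Read catFISH CSV (animal_id,group,n_vgat,n_exon,n_intron,n_both)
#' @param path file path.
#' @return a `catfish_counts`.
#' @export
read_catfish <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  catfish_counts(d$animal_id, d$group, d$n_vgat, d$n_exon, d$n_intron,
                 d$n_both)
}

#' catFISH convergence rate
#'
#' Fraction of second-stimulus-activated (intron+) cells that were also
#' first-stimulus-activated (exon+): `n_both / n_intron`.
#'
#' @param counts a `catfish_counts`, or `n_both` as a bare count.
#' @param n_intron intron+ count (scalar form).
#' @return per-animal fractions (vector form) or a scalar; `NA` with a
#'   warning when `n_intron` is 0.
#' @export
convergence_rate <- function(counts, n_intron = NULL) {
  if (inherits(counts, "catfish_counts")) {
    n_both <- counts$n_both; n_intron <- counts$n_intron
  } else n_both <- counts
  if (any(n_intron == 0)) warning("n_intron = 0: convergence rate undefined")
  ifelse(n_intron > 0, n_both / n_intron, NA_real_)
}

#' catFISH chance level
#'
#' The independence expectation of the convergence rate: the
#' first-stimulus activation fraction `n_exon / n_vgat`.  When first- and
#' second-epoch activation are independent, the convergence rate equals
#' this value in expectation.
#'
#' @param counts a `catfish_counts`, or `n_exon` as a bare count.
#' @param n_vgat total counted cells (scalar form).
#' @return per-animal fractions or a scalar.
#' @export
chance_level <- function(counts, n_vgat = NULL) {
  if (inherits(counts, "catfish_counts")) {
    n_exon <- counts$n_exon; n_vgat <- counts$n_vgat
  } else n_exon <- counts
  if (any(n_vgat == 0)) stop("n_vgat must be positive")
  n_exon / n_vgat
}

#' Compare per-animal convergence rates to their chance levels
#'
#' Reports per-group mean +/- SEM of the convergence rate, the per-animal
#' difference (rate - chance), and a per-animal exact binomial test of
#' `n_both` successes in `n_intron` trials against `p = chance`
#' (one-sided, greater: the scientific question is whether convergence
#' exceeds chance).
#'
#' @param counts a `catfish_counts` with at least 2 animals (a single
#'   animal yields descriptive output with a warning).
#' @return list with `per_animal` (data frame: rate, chance, difference,
#'   binom_p) and `per_group` (mean, sem, n per group).
#' @export
compare_to_chance <- function(counts) {
  stopifnot(inherits(counts, "catfish_counts"))
  rate <- convergence_rate(counts)
  chance <- chance_level(counts)
  binom_p <- vapply(seq_len(nrow(counts)), function(i) {
    if (counts$n_intron[i] == 0) return(NA_real_)
    stats::binom.test(counts$n_both[i], counts$n_intron[i],
                      p = chance[i], alternative = "greater")$p.value
  }, numeric(1))
  per_animal <- data.frame(animal_id = counts$animal_id,
                           group = counts$group, rate = rate,
                           chance = chance, difference = rate - chance,
                           binom_p = binom_p, stringsAsFactors = FALSE)
  if (nrow(counts) < 2)
    warning("single animal: descriptive output only")
  groups <- unique(counts$group)
  per_group <- data.frame(
    group = groups,
    mean_rate = vapply(groups, function(g) mean(rate[counts$group == g],
                                                na.rm = TRUE), numeric(1)),
    sem_rate = vapply(groups, function(g) sem(rate[counts$group == g]),
                      numeric(1)),
    mean_chance = vapply(groups, function(g)
      mean(chance[counts$group == g]), numeric(1)),
    n = vapply(groups, function(g) sum(counts$group == g), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_animal = per_animal, per_group = per_group)
}

#' Retrograde-tracing input fractions
#'
#' Percentage of retrogradely labeled (dsRed+) cells per upstream region:
#' each region's count divided by the total labeled cells counted outside
#' the injection site, times 100.
#'
#' @param counts data frame with columns `region`, `count` (and optionally
#'   `animal_id` for per-animal fractions).
#' @return data frame `region`, `pct` (and `animal_id` when present);
#'   percentages sum to 100 per animal.
#' @export
input_fractions <- function(counts) {
  stopifnot(all(c("region", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be nonnegative")
  one <- function(d) {
    tot <- sum(d$count)
    if (tot == 0) stop("total labeled cell count is zero")
    data.frame(region = d$region, pct = 100 * d$count / tot,
               stringsAsFactors = FALSE)
  }
  if ("animal_id" %in% names(counts)) {
    parts <- lapply(split(counts, counts$animal_id), one)
    out <- do.call(rbind, Map(function(id, d)
      cbind(animal_id = id, d), names(parts), parts))
    rownames(out) <- NULL
    out
  } else one(counts)
}

#' Patch-clamp connection rate
#'
#' Percentage of recorded cells showing a light-evoked synaptic response.
#'
#' @param n_responsive number of responsive cells.
#' @param n_recorded number of recorded cells.
#' @return percentage.
#' @examples
#' connection_rate(11, 35)  # ~31%
#' @export
connection_rate <- function(n_responsive, n_recorded) {
  stopifnot(n_recorded > 0, n_responsive >= 0, n_responsive <= n_recorded)
  100 * n_responsive / n_recorded
}
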