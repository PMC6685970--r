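#' Specification of synthetic per-section cell-count tables
#'
#' Emulates manual OSN/cell counts per coronal section: independent Poisson
#' counts with a per-group mean, several sections per animal, several animals
#' per group.
#'
#' @param lambda named numeric vector of per-group Poisson means
#'   (cells/section), all >= 0.
#' @param sections_per_animal sections counted per animal.
#' @param animals_per_group animals per group.
#' @param seed integer RNG seed.
#' @return object of class `count_spec`.
#' @export
count_spec <- function(lambda = c(control = 30, mutant = 10),
                       sections_per_animal = 10L, animals_per_group = 3L,
                       seed = 1L) {
  stopifnot(all(lambda >= 0), sections_per_animal >= 1, animals_per_group >= 1)
  if (is.null(names(lambda)))
    names(lambda) <- paste0("group", seq_along(lambda))
  structure(list(lambda = lambda,
                 sections_per_animal = as.integer(sections_per_animal),
                 animals_per_group = as.integer(animals_per_group),
                 seed = as.integer(seed)),
            class = "count_spec")
}

#' Generate a synthetic cell-count table
#'
#' @param spec a [count_spec()].
#' @return data.frame `group`, `animal`, `section`, `count`; counts are
#'   independent Poisson draws with the group's mean, reproducible by seed.
#' @export
gen_counts <- function(spec) {
  stopifnot(inherits(spec, "count_spec"))
  set.seed(spec$seed)
  out <- expand.grid(section = seq_len(spec$sections_per_animal),
                     animal = seq_len(spec$animals_per_group),
                     group = names(spec$lambda),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("group", "animal", "section")]
  out$animal <- paste(out$group, out$animal, sep = "_")
  out$count <- rpois(nrow(out), spec$lambda[out$group])
  out
}

#' Per-animal then per-group summary of a count table
#'
#' Animals are the unit of replication: section counts are averaged per
#' animal first, then summarized as mean +/- s.e.m. across animals.
#'
#' @param counts a count table from [gen_counts()] (or any data.frame with
#'   `group`, `animal`, `count`).
#' @return data.frame `group`, `mean`, `sem`, `n` (animals).
#' @export
summarize_counts <- function(counts) {
  per_animal <- aggregate(count ~ group + animal, counts, mean)
  agg <- aggregate(count ~ group, per_animal,
                   function(v) c(mean = mean(v), sem = sd(v) / sqrt(length(v)),
                                 n = length(v)))
  data.frame(group = agg$group,
             mean = agg$count[, "mean"],
             sem = agg$count[, "sem"],
             n = as.integer(agg$count[, "n"]))
}
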