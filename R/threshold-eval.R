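#' Three-way assignment from an ancestry coefficient
#'
#' The management rule applied to a two-cluster ancestry coefficient:
#' an individual is nonadmixed taxon A when `q >= T`, nonadmixed taxon B
#' when `1 - q >= T`, and a hybrid otherwise. Equality counts as nonadmixed
#' (an animal exactly at the threshold is retained).
#'
#' @param q numeric vector of ancestry coefficients for cluster A, in
#'   `[0, 1]`.
#' @param threshold a single threshold in `(0.5, 1)`.
#' @return character vector over `{"PURE_A", "PURE_B", "HYBRID"}`.
#' @export
assign_structure_threshold <- function(q, threshold) {
  if (threshold <= 0.5 || threshold >= 1) {
    stop("threshold must be in (0.5, 1)")
  }
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  out <- rep("HYBRID", length(q))
  out[q >= threshold] <- "PURE_A"
  out[(1 - q) >= threshold] <- "PURE_B"
  out
}

# truth labels collapsed to the three-way scheme; hybrid classes pooled
collapse_truth <- function(truth) {
  ifelse(truth == "PURE_A", "PURE_A",
         ifelse(truth == "PURE_B", "PURE_B", "HYBRID"))
}

# assigned labels collapsed: any six-way hybrid category or OTHER counts as
# a hybrid assignment
collapse_assigned <- function(assigned) {
  ifelse(assigned == "PURE_A", "PURE_A",
         ifelse(assigned == "PURE_B", "PURE_B", "HYBRID"))
}

#' Efficiency, accuracy and performance of category assignment
#'
#' Efficiency: of the individuals truly in the category, the fraction
#' assigned to it. Accuracy: of the individuals assigned to the category,
#' the fraction truly in it (0 when nothing is assigned). Performance is
#' their product, the single-number summary of the efficiency/accuracy
#' trade-off.
#'
#' @param truth,assigned character vectors over the same individuals;
#'   `category` is evaluated against both.
#' @param category the category label to evaluate. The merged `"HYBRID"`
#'   category pools every hybrid pedigree class in `truth` and every
#'   non-pure assignment (including `"OTHER"`).
#' @return one-row data frame: `n_simulated`, `n_assigned`, `n_correct`,
#'   `efficiency`, `accuracy`, `performance`.
#' @export
efficiency_accuracy <- function(truth, assigned, category) {
  if (length(truth) != length(assigned)) {
    stop("truth and assigned must cover the same individuals")
  }
  tru <- if (category %in% c("PURE_A", "PURE_B", "HYBRID"))
    collapse_truth(truth) else truth
  asg <- if (category %in% c("PURE_A", "PURE_B", "HYBRID"))
    collapse_assigned(assigned) else assigned
  n_sim <- sum(tru == category)
  if (n_sim == 0L) stop("category '", category, "' absent from truth: ",
                        "efficiency undefined")
  n_asg <- sum(asg == category)
  n_cor <- sum(tru == category & asg == category)
  eff <- n_cor / n_sim
  acc <- if (n_asg == 0L) 0 else n_cor / n_asg
  data.frame(category = category, n_simulated = n_sim, n_assigned = n_asg,
             n_correct = n_cor, efficiency = eff, accuracy = acc,
             performance = eff * acc, stringsAsFactors = FALSE)
}

#' Threshold grid used throughout the evaluation
#'
#' @param from,to,by grid bounds and step (defaults 0.86-0.99 by 0.01,
#'   endpoints inclusive).
#' @return numeric vector of thresholds.
#' @export
threshold_grid <- function(from = 0.86, to = 0.99, by = 0.01) {
  g <- seq(from, to, by = by)
  if (length(g) == 0L) stop("empty threshold grid")
  if (any(g <= 0.5 | g >= 1)) stop("grid must lie within (0.5, 1)")
  round(g, 10)
}

#' Efficiency/accuracy/performance over a threshold grid
#'
#' Applies the chosen assignment rule at every threshold of the grid and
#' tabulates [efficiency_accuracy()] for the three-way categories (PURE_A,
#' PURE_B, merged HYBRID), on the full dataset and, when double backcrosses
#' are present, on the subset excluding them (they are the hardest class and
#' are tallied separately to quantify how much they cost).
#'
#' @param truth character vector of true pedigree classes.
#' @param scores either a `q_estimate` data frame (or numeric vector of Q
#'   values) for `method = "structure_q"`, or a `category_posterior` data
#'   frame for the category-model methods.
#' @param method `"structure_q"` (threshold on Q), `"newhybrids_six"`
#'   (six-way argmax threshold), or `"newhybrids_three"` (three-way
#'   posterior threshold).
#' @param grid numeric threshold vector, see [threshold_grid()].
#' @return a list of class `threshold_evaluation`: `table` (tidy per
#'   threshold x category x subset data frame), `method`, `grid`.
#' @export
threshold_scan <- function(truth, scores, method = c("structure_q",
                                                     "newhybrids_six",
                                                     "newhybrids_three"),
                           grid = threshold_grid()) {
  method <- match.arg(method)
  if (length(grid) == 0L) stop("empty threshold grid")
  assign_at <- function(threshold) {
    switch(method,
      structure_q = assign_structure_threshold(
        if (is.data.frame(scores)) scores$Q else scores, threshold),
      newhybrids_six = map_category_assignment(scores, threshold,
                                               scheme = "six_way"),
      newhybrids_three = map_category_assignment(scores, threshold,
                                                 scheme = "three_way"))
  }
  keep_bc2 <- !(truth %in% c("BC2_A", "BC2_B"))
  subsets <- list(all = rep(TRUE, length(truth)))
  if (any(!keep_bc2)) subsets$no_bc2 <- keep_bc2
  rows <- list()
  for (Tq in grid) {
    asg <- assign_at(Tq)
    for (s in names(subsets)) {
      sel <- subsets[[s]]
      for (cat in c("PURE_A", "PURE_B", "HYBRID")) {
        if (!cat %in% collapse_truth(truth[sel])) next
        r <- efficiency_accuracy(truth[sel], asg[sel], cat)
        r$threshold <- Tq
        r$subset <- s
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab[, c("threshold", "subset", "category",
                                 "n_simulated", "n_assigned", "n_correct",
                                 "efficiency", "accuracy", "performance")],
                 method = method, grid = grid),
            class = "threshold_evaluation")
}

#' Removal-consequence curves over a threshold grid
#'
#' The culling rule retains only individuals assigned nonadmixed taxon A
#' (`q >= T`); everyone else — hybrids and taxon B alike — is removed. For
#' each threshold the curve reports the fraction of each true class removed,
#' the fraction of true pure A wrongly removed, the fraction of each hybrid
#' class escaping removal, and the overall removal fraction.
#'
#' @param truth character vector of true classes.
#' @param q numeric Q values (or a `q_estimate` data frame).
#' @param grid threshold vector.
#' @return a list of class `removal_curve`: `per_class` (threshold x class
#'   removal fractions, long format) and `overall` (per threshold: overall
#'   removal fraction, pure-A wrongly-removed fraction, hybrid
#'   not-removed fraction).
#' @export
removal_curve <- function(truth, q, grid = threshold_grid()) {
  if (is.data.frame(q)) q <- q$Q
  if (length(truth) != length(q)) stop("truth and q must be aligned")
  per_class <- list()
  overall <- list()
  hyb <- collapse_truth(truth) == "HYBRID"
  for (Tq in grid) {
    removed <- assign_structure_threshold(q, Tq) != "PURE_A"
    for (cl in unique(truth)) {
      sel <- truth == cl
      per_class[[length(per_class) + 1L]] <- data.frame(
        threshold = Tq, class = cl, n = sum(sel),
        removed_fraction = mean(removed[sel]))
    }
    overall[[length(overall) + 1L]] <- data.frame(
      threshold = Tq,
      overall_removed = mean(removed),
      pure_A_removed = if (any(truth == "PURE_A"))
        mean(removed[truth == "PURE_A"]) else NA_real_,
      hybrid_not_removed = if (any(hyb)) mean(!removed[hyb]) else NA_real_)
  }
  structure(list(per_class = do.call(rbind, per_class),
                 overall = do.call(rbind, overall), grid = grid),
            class = "removal_curve")
}

#' Per-location composition of assignments
#'
#' Summarizes three-way labels by sampling location, keeping locations with
#' at least `min_n` individuals, and counts the locations containing only
#' nonadmixed taxon A.
#'
#' @param labels character vector of three-way labels (`PURE_A`, `PURE_B`,
#'   `HYBRID`; six-way labels are collapsed).
#' @param locations character vector of location names, aligned with
#'   `labels`.
#' @param min_n minimum individuals per reported location (default 10).
#' @return a list: `table` (location, n, fraction per label) and
#'   `n_all_pure_A` (count of retained locations with 100% PURE_A).
#' @export
location_composition <- function(labels, locations, min_n = 10L) {
  if (length(labels) != length(locations)) {
    stop("labels and locations must be aligned")
  }
  lab <- collapse_assigned(labels)
  tab <- table(locations)
  keep <- names(tab)[tab >= min_n]
  rows <- lapply(keep, function(loc) {
    sel <- locations == loc
    data.frame(location = loc, n = sum(sel),
               frac_pure_A = mean(lab[sel] == "PURE_A"),
               frac_pure_B = mean(lab[sel] == "PURE_B"),
               frac_hybrid = mean(lab[sel] == "HYBRID"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(location = character(0), n = integer(0),
               frac_pure_A = numeric(0), frac_pure_B = numeric(0),
               frac_hybrid = numeric(0))
  list(table = out, n_all_pure_A = sum(out$frac_pure_A == 1))
}

#' Compare three-way assignments from two methods
#'
#' @param assignments_1,assignments_2 character label vectors (or data
#'   frames with `id` and `label`) over the same individuals.
#' @param ids optional ids used to align plain vectors.
#' @return a list: `n_differ`, `fraction_differ`, `n`.
#' @export
compare_methods <- function(assignments_1, assignments_2, ids = NULL) {
  get <- function(x) {
    if (is.data.frame(x)) {
      list(id = x$id, lab = collapse_assigned(x$label))
    } else {
      list(id = ids, lab = collapse_assigned(x))
    }
  }
  a1 <- get(assignments_1); a2 <- get(assignments_2)
  if (!is.null(a1$id) && !is.null(a2$id)) {
    i <- match(a1$id, a2$id)
    if (anyNA(i)) stop("assignment sets cover different individuals")
    a2$lab <- a2$lab[i]
  }
  if (length(a1$lab) != length(a2$lab)) {
    stop("assignment sets cover different individuals")
  }
  d <- sum(a1$lab != a2$lab)
  list(n_differ = d, fraction_differ = d / length(a1$lab),
       n = length(a1$lab))
}
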