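#' Construct a genotype dataset
#'
#' The central container of the package: diploid multilocus microsatellite
#' genotypes for a set of individuals, each belonging to a group (a sampling
#' location or a reference population) and optionally carrying a known
#' pedigree class (for simulated individuals).
#'
#' Calls are stored as an integer matrix with two columns per locus; allele
#' values are fragment sizes in base pairs. A genotype is an unordered pair:
#' all operations in the package ignore the within-pair column order.
#' `NA` encodes a missing call (both gene copies of a locus are missing
#' together, the usual situation for failed microsatellite amplification).
#'
#' @param ids character vector of individual identifiers (unique).
#' @param group character vector of group labels, recycled if length 1.
#' @param loci character vector of locus names.
#' @param alleles integer matrix, `length(ids)` rows and `2 * length(loci)`
#'   columns (locus-major: columns 1,2 are locus 1). Positive integers or NA.
#' @param truth optional character vector of true pedigree classes
#'   (see [hybrid_class_labels()]), or `NULL`.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(ids, group, loci, alleles, truth = NULL) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  n <- length(ids)
  L <- length(loci)
  if (length(group) == 1L) group <- rep(group, n)
  group <- as.character(group)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != n || ncol(alleles) != 2L * L) {
    stop("alleles must be a ", n, " x ", 2L * L, " matrix")
  }
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(group) != n) stop("group must have one label per individual")
  bad <- !is.na(alleles) & alleles <= 0L
  if (any(bad)) stop("allele sizes must be positive integers")
  # missingness is per call slot: half-missing genotypes are not allowed
  a1 <- alleles[, seq(1L, 2L * L, by = 2L), drop = FALSE]
  a2 <- alleles[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  if (any(is.na(a1) != is.na(a2))) {
    stop("a call must be either fully observed or fully missing")
  }
  if (!is.null(truth)) {
    truth <- as.character(truth)
    if (length(truth) != n) stop("truth must have one label per individual")
  }
  dimnames(alleles) <- list(ids, paste(rep(loci, each = 2L), c("a", "b"),
                                       sep = "."))
  structure(list(ids = ids, group = group, loci = loci,
                 alleles = alleles, truth = truth),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  cat("groups:", paste(utils::head(unique(x$group), 8L), collapse = ", "))
  if (length(unique(x$group)) > 8L) cat(", ...")
  cat("\nmissing calls:",
      sprintf("%.2f%%", 100 * missing_fraction(x)), "\n")
  invisible(x)
}

n_ind <- function(dataset) length(dataset$ids)

missing_fraction <- function(dataset) {
  a1 <- dataset$alleles[, seq(1L, ncol(dataset$alleles), by = 2L),
                        drop = FALSE]
  mean(is.na(a1))
}

#' Subset a genotype dataset by individual
#'
#' @param dataset a [genotype_dataset()].
#' @param idx integer or logical index over individuals.
#' @return a `genotype_dataset` with the selected individuals.
#' @export
subset_individuals <- function(dataset, idx) {
  genotype_dataset(dataset$ids[idx], dataset$group[idx], dataset$loci,
                   dataset$alleles[idx, , drop = FALSE],
                   truth = if (!is.null(dataset$truth)) dataset$truth[idx])
}

#' Combine genotype datasets sharing the same loci
#'
#' @param ... `genotype_dataset` objects with identical locus vectors.
#' @return a single `genotype_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "genotype_dataset")) ds <- ds[[1]]
  loci <- ds[[1]]$loci
  for (d in ds) {
    if (!identical(d$loci, loci)) stop("datasets must share identical loci")
  }
  truth <- lapply(ds, function(d) {
    if (is.null(d$truth)) rep(NA_character_, n_ind(d)) else d$truth
  })
  truth <- unlist(truth)
  if (all(is.na(truth))) truth <- NULL
  genotype_dataset(unlist(lapply(ds, `[[`, "ids")),
                   unlist(lapply(ds, `[[`, "group")), loci,
                   do.call(rbind, lapply(ds, `[[`, "alleles")),
                   truth = truth)
}

## ---------------------------------------------------------------------------
## File formats

#' Read a GenePop genotype file
#'
#' Parses the classic GenePop dialect: a title line, one locus name per line
#' (or a single comma-separated line), `pop` separator lines, and individual
#' records `id , 0101 0202 ...` with 2- or 3-digit allele coding. The code
#' `00`/`000` is the missing-allele convention and becomes a missing call.
#' Groups are the GenePop pops, named after the id of each pop's last
#' individual (the usual convention) unless ids repeat, in which case pops are
#' numbered.
#'
#' @param path path to a GenePop file.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("GenePop parse error at line 1: file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("GenePop parse error: no 'pop' line found")
  if (first_pop < 3L) {
    stop("GenePop parse error at line ", first_pop, ": no loci before 'pop'")
  }
  header <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)

  pop_of <- cumsum(is_pop)
  rec_idx <- which(pop_of >= 1L & !is_pop & nzchar(trimws(lines)))
  if (length(rec_idx) == 0L) stop("GenePop parse error: no individuals")

  ids <- character(0); grp <- integer(0)
  geno <- matrix(NA_integer_, nrow = length(rec_idx), ncol = 2L * L)
  width <- NA_integer_
  for (r in seq_along(rec_idx)) {
    ln <- rec_idx[r]
    parts <- strsplit(lines[ln], ",")[[1]]
    if (length(parts) < 2L) {
      stop("GenePop parse error at line ", ln, ": expected 'id , genotypes'")
    }
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != L) {
      stop("GenePop parse error at line ", ln, ": expected ", L,
           " genotypes, found ", length(codes))
    }
    w <- unique(nchar(codes)) / 2
    if (length(unique(nchar(codes))) != 1L || !(w[1] %in% c(2, 3))) {
      stop("GenePop format error at line ", ln,
           ": inconsistent allele-code width")
    }
    if (is.na(width)) width <- as.integer(w[1])
    if (w[1] != width) {
      stop("GenePop format error at line ", ln,
           ": allele-code width differs from earlier records")
    }
    a1 <- as.integer(substr(codes, 1L, width))
    a2 <- as.integer(substr(codes, width + 1L, 2L * width))
    miss <- a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    geno[r, seq(1L, 2L * L, by = 2L)] <- a1
    geno[r, seq(2L, 2L * L, by = 2L)] <- a2
    ids <- c(ids, id); grp <- c(grp, pop_of[ln])
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  # name pops after the last individual of each pop (GenePop convention)
  pop_names <- vapply(split(ids, grp), function(v) v[length(v)], "")
  group <- pop_names[as.character(grp)]
  genotype_dataset(ids, group, loci, geno)
}

#' Write a GenePop genotype file
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @param title title line content.
#' @param digits allele-code width, 2 or 3 (3 fits fragment sizes up to 999).
#' @return invisibly, `path`.
#' @export
write_genepop <- function(dataset, path, title = "hybriq export",
                          digits = 3L) {
  if (n_ind(dataset) == 0L) stop("cannot write an empty dataset")
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  maxa <- suppressWarnings(max(dataset$alleles, na.rm = TRUE))
  if (is.finite(maxa) && maxa >= 10^digits) {
    stop("allele sizes do not fit in ", digits, "-digit coding")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(dataset$loci, con)
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  for (g in unique(dataset$group)) {
    writeLines("pop", con)
    for (i in which(dataset$group == g)) {
      row <- dataset$alleles[i, ]
      codes <- paste0(fmt(row[seq(1L, length(row), by = 2L)]),
                      fmt(row[seq(2L, length(row), by = 2L)]))
      writeLines(paste0(dataset$ids[i], " , ", paste(codes, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a STRUCTURE-format genotype table
#'
#' Supports the two layouts in common use: two rows per individual (one gene
#' copy per row) and one row per individual with paired columns. Columns are
#' `id group allele1 allele2 ...`, whitespace-delimited, no header.
#'
#' @param path path to the table.
#' @param rows_per_individual 1 or 2.
#' @param missing_code integer code for a missing allele (default -9).
#' @return a [genotype_dataset()]. Group labels are taken verbatim from the
#'   second column; a sidecar legend written by [write_structure_table()] is
#'   used to restore original labels when present.
#' @export
read_structure_table <- function(path, rows_per_individual = 2L,
                                 missing_code = -9L) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("STRUCTURE format error: need id, group, alleles")
  ids <- tab[[1]]; grp <- tab[[2]]
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "integer")
  if (anyNA(vals)) stop("STRUCTURE format error: non-integer allele entry")
  if (rows_per_individual == 2L) {
    if (nrow(vals) %% 2L != 0L) {
      stop("STRUCTURE format error: odd number of rows for two-row layout")
    }
    odd <- seq(1L, nrow(vals), by = 2L)
    if (!all(ids[odd] == ids[odd + 1L])) {
      stop("STRUCTURE format error: row pairs carry different ids")
    }
    L <- ncol(vals)
    geno <- matrix(NA_integer_, nrow = length(odd), ncol = 2L * L)
    geno[, seq(1L, 2L * L, by = 2L)] <- vals[odd, , drop = FALSE]
    geno[, seq(2L, 2L * L, by = 2L)] <- vals[odd + 1L, , drop = FALSE]
    ids <- ids[odd]; grp <- grp[odd]
  } else if (rows_per_individual == 1L) {
    if (ncol(vals) %% 2L != 0L) {
      stop("STRUCTURE format error: odd allele-column count in one-row layout")
    }
    geno <- vals
  } else stop("rows_per_individual must be 1 or 2")
  geno[geno == missing_code] <- NA_integer_
  # a half-missing call is coerced to fully missing
  L <- ncol(geno) / 2L
  for (l in seq_len(L)) {
    c1 <- 2L * l - 1L
    m <- is.na(geno[, c1]) | is.na(geno[, c1 + 1L])
    geno[m, c(c1, c1 + 1L)] <- NA_integer_
  }
  legend_path <- paste0(path, ".groups")
  if (file.exists(legend_path)) {
    leg <- utils::read.table(legend_path, header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    map <- stats::setNames(leg[[2]], leg[[1]])
    hit <- grp %in% names(map)
    grp[hit] <- map[grp[hit]]
  }
  loci_path <- paste0(path, ".loci")
  loci <- if (file.exists(loci_path)) readLines(loci_path, warn = FALSE)
          else paste0("L", seq_len(ncol(geno) / 2L))
  if (length(loci) != ncol(geno) / 2L) {
    stop("STRUCTURE format error: locus sidecar length mismatch")
  }
  genotype_dataset(ids, grp, loci, geno)
}

#' Write a STRUCTURE two-row genotype table
#'
#' Writes two rows per individual; missing calls become the missing code on
#' both rows. Groups are encoded as integers, with the original labels saved
#' in a sidecar legend file `<path>.groups` and locus names in `<path>.loci`
#' so a round trip preserves them.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @param missing_code integer written for a missing allele (default -9).
#' @return invisibly, `path`.
#' @export
write_structure_table <- function(dataset, path, missing_code = -9L) {
  if (n_ind(dataset) == 0L) stop("cannot write an empty dataset")
  L <- length(dataset$loci)
  groups <- unique(dataset$group)
  gcode <- match(dataset$group, groups)
  a1 <- dataset$alleles[, seq(1L, 2L * L, by = 2L), drop = FALSE]
  a2 <- dataset$alleles[, seq(2L, 2L * L, by = 2L), drop = FALSE]
  a1[is.na(a1)] <- missing_code; a2[is.na(a2)] <- missing_code
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_ind(dataset))) {
    writeLines(paste(c(dataset$ids[i], gcode[i], a1[i, ]), collapse = "\t"),
               con)
    writeLines(paste(c(dataset$ids[i], gcode[i], a2[i, ]), collapse = "\t"),
               con)
  }
  utils::write.table(data.frame(code = seq_along(groups), label = groups),
                     paste0(path, ".groups"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(dataset$loci, paste0(path, ".loci"))
  invisible(path)
}

## ---------------------------------------------------------------------------
## Allele frequencies and diversity

#' Construct an allele-frequency pool
#'
#' A per-locus map from allele size to population frequency, the parametric
#' description of one parental population under Hardy-Weinberg proportions.
#'
#' @param loci character vector of locus names.
#' @param freqs list (one element per locus) of named numeric vectors; names
#'   are allele sizes in base pairs, values are frequencies summing to 1.
#' @return an object of class `allele_freq_pool`.
#' @export
allele_freq_pool <- function(loci, freqs) {
  loci <- as.character(loci)
  if (length(freqs) != length(loci)) stop("one frequency vector per locus")
  names(freqs) <- loci
  for (l in loci) {
    f <- freqs[[l]]
    if (length(f) < 1L) stop("locus ", l, " has no alleles")
    if (is.null(names(f)) || anyNA(suppressWarnings(as.integer(names(f))))) {
      stop("locus ", l, ": allele names must be integer sizes")
    }
    if (any(f < 0)) stop("locus ", l, ": negative frequency")
    if (abs(sum(f) - 1) > 1e-9) {
      stop("locus ", l, ": frequencies sum to ", sum(f), ", not 1")
    }
    # drop zero-frequency alleles; they carry no information
    freqs[[l]] <- f[f > 0]
  }
  structure(list(loci = loci, freqs = freqs), class = "allele_freq_pool")
}

#' @export
print.allele_freq_pool <- function(x, ...) {
  A <- vapply(x$freqs, length, 1L)
  cat("allele_freq_pool:", length(x$loci), "loci;",
      "alleles per locus", paste(range(A), collapse = "-"),
      sprintf("; mean He %.3f", mean(pool_he(x))), "\n")
  invisible(x)
}

#' Expected heterozygosity of each locus of a pool
#'
#' Plain (parametric) expected heterozygosity `1 - sum(p^2)` computed from the
#' pool's population frequencies; no finite-sample correction applies because
#' a pool is a population, not a sample.
#'
#' @param pool an [allele_freq_pool()].
#' @return named numeric vector of per-locus He.
#' @export
pool_he <- function(pool) {
  vapply(pool$freqs, function(f) 1 - sum(f^2), 0)
}

#' Estimate allele frequencies for one group of a dataset
#'
#' Counts non-missing gene copies per locus and normalizes. Missing calls are
#' excluded from numerator and denominator.
#'
#' @param dataset a [genotype_dataset()].
#' @param group a group label present in `dataset`, or `NULL` to pool all
#'   individuals.
#' @return an [allele_freq_pool()].
#' @export
allele_frequencies <- function(dataset, group = NULL) {
  idx <- if (is.null(group)) seq_len(n_ind(dataset)) else
    which(dataset$group == group)
  if (length(idx) == 0L) stop("no individuals in group '", group, "'")
  L <- length(dataset$loci)
  freqs <- vector("list", L)
  for (l in seq_len(L)) {
    a <- c(dataset$alleles[idx, 2L * l - 1L], dataset$alleles[idx, 2L * l])
    a <- a[!is.na(a)]
    if (length(a) == 0L) {
      stop("locus ", dataset$loci[l], ": all calls missing in group")
    }
    tab <- table(a)
    f <- as.numeric(tab) / length(a)
    names(f) <- names(tab)
    freqs[[l]] <- f[order(as.integer(names(f)))]
  }
  allele_freq_pool(dataset$loci, freqs)
}

#' Per-locus and overall diversity summary
#'
#' Observed heterozygosity Ho (fraction of non-missing calls with two distinct
#' alleles), expected heterozygosity He, allele count A, and missing fraction,
#' per locus plus an unweighted mean over loci.
#'
#' He defaults to Nei's unbiased estimator `2n/(2n-1) * (1 - sum(p^2))` with
#' `n` the number of diploid individuals scored at the locus (the GenAlEx
#' convention); `unbiased = FALSE` gives the plain `1 - sum(p^2)`.
#'
#' @param dataset a [genotype_dataset()].
#' @param group group label, or `NULL` for all individuals.
#' @param unbiased apply the small-sample correction (default TRUE).
#' @return a list with a per-locus data frame `per_locus` and a one-row
#'   `overall` data frame (unweighted locus means).
#' @export
diversity_stats <- function(dataset, group = NULL, unbiased = TRUE) {
  idx <- if (is.null(group)) seq_len(n_ind(dataset)) else
    which(dataset$group == group)
  if (length(idx) == 0L) stop("empty group '", group, "'")
  L <- length(dataset$loci)
  A <- Ho <- He <- missf <- numeric(L)
  for (l in seq_len(L)) {
    a1 <- dataset$alleles[idx, 2L * l - 1L]
    a2 <- dataset$alleles[idx, 2L * l]
    ok <- !is.na(a1)
    missf[l] <- mean(!ok)
    n <- sum(ok)
    if (n == 0L) stop("locus ", dataset$loci[l], ": all calls missing")
    Ho[l] <- mean(a1[ok] != a2[ok])
    p <- as.numeric(table(c(a1[ok], a2[ok]))) / (2 * n)
    A[l] <- length(p)
    he <- 1 - sum(p^2)
    if (unbiased && n > 1L) he <- he * 2 * n / (2 * n - 1)
    He[l] <- he
  }
  per_locus <- data.frame(locus = dataset$loci, A = A, Ho = Ho, He = He,
                          missing_fraction = missf)
  overall <- data.frame(A = mean(A), Ho = mean(Ho), He = mean(He),
                        missing_fraction = mean(missf))
  list(per_locus = per_locus, overall = overall)
}

## ---------------------------------------------------------------------------
## PCA

#' Individual-level PCA of genotypes
#'
#' Encodes each individual as a vector of per-allele counts (0/1/2, one
#' dimension per allele observed anywhere in the dataset), imputes missing
#' entries to the column mean, centers columns, and eigendecomposes the
#' covariance — the standard individual-by-individual genotype PCA used to
#' visualize divergence between taxa and intermediate (hybrid) individuals.
#'
#' @param dataset a [genotype_dataset()] with at least 3 individuals and 2
#'   loci.
#' @param n_axes number of axes to return (default 2; capped at the rank).
#' @return a list: `scores` (individuals x axes), `explained` (fraction of
#'   total variance per returned axis), `zero_variance` flag (TRUE when all
#'   individuals are identical).
#' @export
pca_individuals <- function(dataset, n_axes = 2L) {
  if (n_ind(dataset) < 3L) stop("PCA needs at least 3 individuals")
  if (length(dataset$loci) < 2L) stop("PCA needs at least 2 loci")
  X <- allele_count_matrix(dataset)
  # mean-impute missing entries per allele column
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mean(X[, j], na.rm = TRUE)
  }
  X[is.nan(X)] <- 0
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) {
    warning("all individuals identical: zero-variance configuration")
    return(list(scores = matrix(0, nrow(X), n_axes,
                                dimnames = list(dataset$ids, NULL)),
                explained = rep(0, n_axes), zero_variance = TRUE))
  }
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- min(n_axes, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- dataset$ids
  list(scores = scores, explained = (ev / sum(ev))[seq_len(k)],
       zero_variance = FALSE)
}

# individuals x (locus,allele) 0/1/2 count matrix; NA rows where call missing
allele_count_matrix <- function(dataset) {
  L <- length(dataset$loci)
  cols <- list()
  for (l in seq_len(L)) {
    a1 <- dataset$alleles[, 2L * l - 1L]
    a2 <- dataset$alleles[, 2L * l]
    sizes <- sort(unique(c(a1, a2)))
    sizes <- sizes[!is.na(sizes)]
    for (s in sizes) {
      v <- (a1 == s) + (a2 == s)
      cols[[paste0(dataset$loci[l], ".", s)]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}
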