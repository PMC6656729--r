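#' Assign accessions to genetic groups from ancestry fractions
#'
#' Applies the majority-ancestry rule used for selfing panels: an accession
#' is assigned to a cluster when strictly more than `threshold` of its genome
#' derives from that cluster; otherwise it is labelled `"Admixed"`. Admixed
#' accessions are excluded from all downstream differentiation statistics.
#'
#' @param q numeric matrix or data.frame of ancestry fractions, one row per
#'   accession (rownames = accession ids), one column per cluster. Rows must
#'   sum to 1 (tolerance 1e-6) with all fractions in \[0, 1\].
#' @param threshold ancestry fraction an accession must exceed (strictly) to
#'   be assigned; default 0.5.
#' @return Named character vector mapping accession id to
#'   `"group_1"` ... `"group_k"` or `"Admixed"`.
#' @export
assign_populations <- function(q, threshold = 0.5) {
  q <- as.matrix(q)
  if (is.null(rownames(q))) stop("q must have accession ids as rownames")
  if (any(q < -1e-9 | q > 1 + 1e-9)) stop("ancestry fractions must lie in [0, 1]")
  rs <- rowSums(q)
  bad <- abs(rs - 1) > 1e-6
  if (any(bad)) {
    stop("ancestry rows not summing to 1: ",
         paste(utils::head(rownames(q)[bad], 5), collapse = ", "))
  }
  top <- max.col(q, ties.method = "first")
  frac <- q[cbind(seq_len(nrow(q)), top)]
  lab <- ifelse(frac > threshold, paste0("group_", top), "Admixed")
  stats::setNames(lab, rownames(q))
}

#' Collapse replicate trait measurements to genotype means
#'
#' Averages replicate-level values on the raw measurement scale, one value
#' per (genotype, trait). Non-finite values are dropped with a warning before
#' averaging.
#'
#' @param traits trait table: data.frame with columns `genotype_id`,
#'   `replicate_id`, `site_id`, `trait`, `value`.
#' @return data.frame with columns `genotype_id`, `site_id`, `trait`,
#'   `value` (one row per genotype x trait present in the input).
#' @export
genotype_means <- function(traits) {
  .check_trait_table(traits)
  bad <- !is.finite(traits$value)
  if (any(bad)) {
    warning(sum(bad), " non-finite trait value(s) dropped before averaging")
    traits <- traits[!bad, , drop = FALSE]
  }
  out <- stats::aggregate(value ~ genotype_id + site_id + trait,
                          data = traits, FUN = mean)
  out[order(out$trait, out$genotype_id), c("genotype_id", "site_id",
                                           "trait", "value")]
}

.check_trait_table <- function(traits, replicated = FALSE) {
  stopifnot(is.data.frame(traits))
  req <- c("genotype_id", "site_id", "trait", "value")
  if (replicated) req <- c(req, "replicate_id")
  miss <- setdiff(req, names(traits))
  if (length(miss)) {
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
  }
  invisible(traits)
}

#' Read a trait table from CSV
#'
#' @param path CSV file with header `genotype_id, replicate_id, site_id,
#'   trait, value`.
#' @return data.frame in trait-table form.
#' @export
read_trait_table <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_trait_table(tt)
  tt
}

#' Read a per-site climate table from CSV
#'
#' @param path CSV file with a `site_id` column and one numeric column per
#'   climate variable.
#' @return data.frame, one row per site.
#' @export
read_climate_table <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(cl)) stop("climate table lacks a site_id column")
  vars <- setdiff(names(cl), "site_id")
  num <- vapply(cl[vars], is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric climate column(s): ",
         paste(vars[!num], collapse = ", "))
  }
  if (anyDuplicated(cl$site_id)) stop("duplicate site_id in climate table")
  cl
}
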