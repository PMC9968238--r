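# Count matrix assembly, expression calling and differential expression of
# circular vs cognate linear splicing events.

#' Build the circular/linear event count matrix
#'
#' Two rows per junction: the circular (back-splice) read count and the
#' cognate linear count, the latter being the sum of reads mapping linearly
#' over the two splice-junction boundaries.  Junctions missing from a sample
#' get zero.
#'
#' @param junction_tables named list (sample -> data.frame with columns
#'   junction_id, circ, linear) as produced by [detect_circrnas()]
#' @param design data.frame(sample, condition, batch)
#' @return integer matrix with rownames `circ:<id>` / `lin:<id>` and one
#'   column per design sample
#' @export
build_matrix <- function(junction_tables, design) {
  stopifnot(all(design$sample %in% names(junction_tables)))
  ids <- sort(unique(unlist(lapply(junction_tables, function(d)
    d$junction_id))))
  m <- matrix(0L, nrow = 2L * length(ids), ncol = nrow(design),
              dimnames = list(c(paste0("circ:", ids), paste0("lin:", ids)),
                              design$sample))
  for (sm in design$sample) {
    d <- junction_tables[[sm]]
    i <- match(d$junction_id, ids)
    m[i, sm] <- as.integer(d$circ)
    m[length(ids) + i, sm] <- as.integer(d$linear)
  }
  m
}

#' Filter events and compute CPM and per-condition expressed sets
#'
#' Events without at least `min_count` reads in at least `min_samples`
#' samples are removed.  CPM uses the column sums of the *full* event matrix
#' as library sizes.  A circRNA is expressed in a condition when its average
#' circular CPM there is >= `cpm_expressed`.
#'
#' @param m event count matrix from [build_matrix()]
#' @param design data.frame(sample, condition, batch)
#' @param min_count,min_samples event filter ("two or more reads in at least
#'   two samples" by default); set `min_samples = NULL` to use the minimum
#'   replicate count across conditions (the pre-test filter)
#' @param cpm_expressed expression-call threshold on the condition-average
#'   CPM
#' @return list(filtered, cpm, lib_sizes, expressed) where expressed is a
#'   named list condition -> character vector of junction ids
#' @export
filter_and_cpm <- function(m, design, min_count = 2L, min_samples = 2L,
                           cpm_expressed = 1) {
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be positive")
  if (is.null(min_samples))
    min_samples <- min(table(design$condition))
  keep <- rowSums(m >= min_count) >= min_samples
  cpm <- t(t(m) / lib) * 1e6
  expressed <- lapply(split(design$sample, design$condition), function(s) {
    circ <- grepl("^circ:", rownames(m))
    avg <- rowMeans(cpm[circ, s, drop = FALSE])
    sub("^circ:", "", rownames(m)[circ][avg >= cpm_expressed])
  })
  list(filtered = m[keep, , drop = FALSE], cpm = cpm, lib_sizes = lib,
       expressed = expressed)
}

#' Exclusive intersection counts of expressed sets (UpSet semantics)
#'
#' @param sets named list of character vectors
#' @return data.frame(combination, count): one row per non-empty membership
#'   pattern, `combination` being the set names joined by `&`; the counts
#'   partition the union
#' @export
intersect_expressed <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  u <- unique(unlist(sets))
  if (!length(u))
    return(data.frame(combination = character(0), count = integer(0)))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1,
                                       dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  tab <- table(pat)
  data.frame(combination = names(tab), count = as.integer(tab),
             row.names = NULL)
}

#' Differential expression of circular and linear events
#'
#' Filters events (at least `min_count` reads in at least the minimum
#' replicate number of samples), estimates dispersion, fits the additive NB
#' GLM (`~ batch + condition`) and runs the LRT, applying the circular
#' (default 0.05) and linear (default 0.1) significance thresholds.
#'
#' @param m event count matrix
#' @param design data.frame(sample, condition, batch)
#' @param alpha_circ,alpha_lin significance thresholds
#' @param min_count pre-test filter count
#' @return list(circ, linear, dispersion, lib_sizes): `circ` and `linear`
#'   are [nb_glm_lrt()] tables keyed by junction id, with a `fdr` column
#'   (BH) added
#' @export
de_analysis <- function(m, design, alpha_circ = 0.05, alpha_lin = 0.1,
                        min_count = 2L) {
  fc <- filter_and_cpm(m, design, min_count = min_count, min_samples = NULL)
  filt <- fc$filtered
  disp <- estimate_dispersion(filt, design, lib_sizes = fc$lib_sizes)
  res <- nb_glm_lrt(filt, design, disp$dispersion,
                    lib_sizes = fc$lib_sizes, alpha = alpha_circ)
  circ <- res[grepl("^circ:", res$event_id), ]
  lin <- res[grepl("^lin:", res$event_id), ]
  # status recall at the linear threshold
  lin$status <- "unaffected"
  lin$status[lin$p_value < alpha_lin & lin$log2fc > 0] <- "up"
  lin$status[lin$p_value < alpha_lin & lin$log2fc < 0] <- "down"
  circ$junction_id <- sub("^circ:", "", circ$event_id)
  lin$junction_id <- sub("^lin:", "", lin$event_id)
  circ$fdr <- stats::p.adjust(circ$p_value, "BH")
  lin$fdr <- stats::p.adjust(lin$p_value, "BH")
  rownames(circ) <- rownames(lin) <- NULL
  list(circ = circ, linear = lin, dispersion = disp,
       lib_sizes = fc$lib_sizes)
}

#' Classify circular vs linear concordance
#'
#' Classes: circ-only (only the circRNA deregulated), linear-only,
#' both-concordant (both significant at their thresholds with the same
#' log2FC sign), both-discordant, neither.
#'
#' @param circ,linear [nb_glm_lrt()]-style tables with junction_id, log2fc,
#'   p_value
#' @param alpha_circ,alpha_lin thresholds (0.05 / 0.1)
#' @return data.frame(junction_id, circ_log2fc, circ_p, lin_log2fc, lin_p,
#'   class)
#' @export
classify_concordance <- function(circ, linear, alpha_circ = 0.05,
                                 alpha_lin = 0.1) {
  i <- match(circ$junction_id, linear$junction_id)
  lfc2 <- linear$log2fc[i]
  p2 <- linear$p_value[i]
  sig1 <- circ$p_value < alpha_circ
  sig2 <- !is.na(p2) & p2 < alpha_lin
  cls <- rep("neither", nrow(circ))
  cls[sig1 & !sig2] <- "circ-only"
  cls[!sig1 & sig2] <- "linear-only"
  same <- sign(circ$log2fc) == sign(lfc2)
  cls[sig1 & sig2 & same] <- "both-concordant"
  cls[sig1 & sig2 & !same] <- "both-discordant"
  data.frame(junction_id = circ$junction_id, circ_log2fc = circ$log2fc,
             circ_p = circ$p_value, lin_log2fc = lfc2, lin_p = p2,
             class = cls)
}

#' Summarise concordance of deregulated circRNAs
#'
#' Deregulated = circRNA significant at its threshold (classes circ-only,
#' both-concordant, both-discordant); the reported percentage is the share
#' of those that are both-concordant, rounded to the nearest integer.
#'
#' @param concordance data.frame from [classify_concordance()]
#' @return list(n_deregulated, n_down, n_up, n_concordant_down,
#'   n_concordant_up, percent_concordant)
#' @export
concordance_summary <- function(concordance) {
  dereg <- concordance$class %in% c("circ-only", "both-concordant",
                                    "both-discordant")
  down <- dereg & concordance$circ_log2fc < 0
  up <- dereg & concordance$circ_log2fc > 0
  conc <- concordance$class == "both-concordant"
  list(n_deregulated = sum(dereg),
       n_down = sum(down), n_up = sum(up),
       n_concordant_down = sum(conc & down),
       n_concordant_up = sum(conc & up),
       percent_concordant = round(100 * sum(conc & dereg) / max(1, sum(dereg))))
}
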