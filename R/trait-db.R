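# Curation of heterogeneous literature trait records into one numeric
# taxon x trait table. The vocabulary covers the 16 genomic, physiological
# and life-history traits commonly curated for gut bacteria; cell sizes are
# carried on the log scale, oxygen tolerance on a 0-5 ordinal scale
# anchored at obligate anaerobe (0) and obligate aerobe (5).

#' The curated trait vocabulary
#'
#' Sixteen bacterial traits with their measurement kind, bounds and
#' transform. `kind` drives aggregation ([aggregate_records()]): continuous
#' and bounded-score traits are averaged, ordinal and binary-probabilistic
#' traits take the mode. `inferable = FALSE` marks traits known to lack
#' phylogenetic conservatism (aggregation score, IgA binding, pH and salt
#' optima), retained in curation but flagged for downstream exclusion.
#'
#' @return data.frame with columns `trait`, `kind`, `lower`, `upper`,
#'   `transform`, `units`, `inferable`.
#' @export
trait_vocabulary <- function() {
  data.frame(
    trait = c("aggregation_score", "b_vitamins", "gene_copies_16s",
              "gc_content", "gene_number", "genome_size", "gram_positive",
              "iga_binding", "length", "motility", "oxygen_tolerance",
              "ph_optimum", "salt_optimum", "sporulation_score",
              "temperature_optimum", "width"),
    kind = c("bounded-score", "continuous", "continuous", "continuous",
             "continuous", "continuous", "binary-probabilistic",
             "continuous", "continuous", "bounded-score", "ordinal",
             "continuous", "continuous", "bounded-score", "continuous",
             "continuous"),
    lower = c(0, 0, 0, 0, 0, 0, 0, NA, NA, 0, 0, NA, 0, 0, NA, NA),
    upper = c(1, NA, NA, 100, NA, NA, 1, NA, NA, 1, 5, NA, NA, 1, NA, NA),
    transform = c("identity", "identity", "identity", "identity",
                  "identity", "identity", "identity", "identity", "log",
                  "identity", "identity", "identity", "identity",
                  "identity", "identity", "log"),
    units = c("score 0-1", "pathways", "copies", "percent", "genes", "Mb",
              "score 0-1", "log coating index", "log um", "score 0-1",
              "ordinal 0-5", "pH", "g/l", "score 0-1", "degrees C",
              "log um"),
    inferable = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                  TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# mode of a numeric vector; ties resolved by averaging the tied values
.num_mode <- function(v) {
  tab <- table(v)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  mean(modes)
}

#' Construct a trait table with per-cell provenance
#'
#' @param values Numeric matrix, taxa x traits (row/col names required).
#' @param provenance Character matrix of the same shape with entries
#'   `"observed"`, `"predicted"` or `"missing"`; defaults to `"observed"`
#'   where `values` is non-`NA` and `"missing"` elsewhere.
#' @param meta Per-trait metadata; defaults to the matching rows of
#'   [trait_vocabulary()] (unknown trait names get kind `"continuous"`).
#' @return Object of class `trait_table` with elements `values`,
#'   `provenance`, `meta`.
#' @export
trait_table <- function(values, provenance = NULL, meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs row (taxon) and column (trait) names", call. = FALSE)
  if (is.null(provenance))
    provenance <- ifelse(is.na(values), "missing", "observed")
  provenance <- as.matrix(provenance)
  stopifnot(identical(dim(provenance), dim(values)))
  if (!all(provenance %in% c("observed", "predicted", "missing")))
    stop("provenance entries must be observed/predicted/missing", call. = FALSE)
  if (is.null(meta)) {
    voc <- trait_vocabulary()
    meta <- voc[match(colnames(values), voc$trait), ]
    meta$trait <- colnames(values)
    meta$kind[is.na(meta$kind)] <- "continuous"
    rownames(meta) <- NULL
  }
  structure(list(values = values, provenance = provenance, meta = meta),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$values), "taxa x", ncol(x$values), "traits\n")
  tab <- apply(x$provenance, 2, function(p) table(factor(
    p, levels = c("observed", "predicted", "missing"))))
  print(t(tab))
  invisible(x)
}

#' Aggregate raw trait records into one value per taxon and trait
#'
#' Continuous and bounded-score traits take the arithmetic mean of their
#' records; ordinal and binary-probabilistic traits take the mode (ties
#' averaged, which keeps scores in range). Length and width records,
#' supplied in micrometres, are log-transformed before averaging, so the
#' table carries them in log-um units.
#'
#' @param records data.frame with columns `taxon`, `trait`, `value` and
#'   optionally `source`. Values must be numeric (use [encode_discrete()]
#'   and [impute_sporulation()] first for categorical records).
#' @return A [trait_table()] whose cells are `observed` where records
#'   exist.
#' @export
aggregate_records <- function(records) {
  voc <- trait_vocabulary()
  bad <- setdiff(unique(records$trait), voc$trait)
  if (length(bad))
    stop("schema-error: unknown trait name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(records$value))
    stop("parse-error: `value` must be numeric", call. = FALSE)
  taxa <- sort(unique(records$taxon))
  vals <- matrix(NA_real_, length(taxa), nrow(voc),
                 dimnames = list(taxa, voc$trait))
  for (tr in unique(records$trait)) {
    kind <- voc$kind[voc$trait == tr]
    transform <- voc$transform[voc$trait == tr]
    sub <- records[records$trait == tr, ]
    v <- sub$value
    if (transform == "log") {
      if (any(v <= 0))
        stop("parse-error: nonpositive size for log-scale trait ", tr,
             call. = FALSE)
      v <- log(v)
    }
    agg <- tapply(v, sub$taxon,
                  if (kind %in% c("ordinal", "binary-probabilistic"))
                    .num_mode else mean)
    vals[names(agg), tr] <- agg
  }
  trait_table(vals)
}

#' Impute a sporulation score from presence/absence observations
#'
#' Quantitative sporulation scores pass through unchanged and take
#' precedence over binary flags. A bare "spores present" record maps to
#' 0.549 — the median score of taxa with nonzero sporulation ability in
#' the quantitative reference assay — and "spores absent" maps to 0.
#'
#' @param record_flag Character `"spores_present"` / `"spores_absent"`, or
#'   a numeric score in `[0, 1]`. Vectorized; a numeric element paired with
#'   a flag elsewhere keeps the numeric.
#' @return Numeric sporulation score(s).
#' @export
impute_sporulation <- function(record_flag) {
  out <- vapply(record_flag, function(f) {
    if (is.numeric(f)) return(as.numeric(f))
    v <- suppressWarnings(as.numeric(f))
    if (!is.na(v)) return(v)
    switch(as.character(f),
           spores_present = 0.549,
           spores_absent = 0,
           stop("vocabulary-error: unknown sporulation flag ", f,
                call. = FALSE))
  }, numeric(1), USE.NAMES = FALSE)
  out
}

.discrete_vocab <- list(
  gram_positive = c("negative" = 0, "gram-negative" = 0, "positive" = 1,
                    "gram-positive" = 1, "variable" = 0.5),
  motility = c("never motile" = 0, "nonmotile" = 0, "non-motile" = 0,
               "sometimes motile" = 0.5, "motile" = 1, "always motile" = 1),
  aggregation_score = c("never" = 0, "sometimes" = 0.5, "observed" = 1),
  oxygen_tolerance = c("obligate anaerobe" = 0, "anaerobe" = 1,
                       "facultative anaerobe" = 2, "microaerophile" = 3,
                       "aerotolerant" = 3, "aerobe" = 4,
                       "obligate aerobe" = 5))

#' Encode a categorical trait token as its numeric score
#'
#' Deterministic token-to-number maps: Gram stain 0/1 (0.5 for variable),
#' motility and aggregation on 0-1 with 0.5 for intermediate reports, and
#' oxygen tolerance on the ordinal 0-5 scale from obligate anaerobe (0)
#' through facultative anaerobe (2) to obligate aerobe (5).
#'
#' @param trait Trait name (must have a categorical vocabulary).
#' @param token Token string (case-insensitive).
#' @return Numeric encoding.
#' @export
encode_discrete <- function(trait, token) {
  vocab <- .discrete_vocab[[trait]]
  if (is.null(vocab))
    stop("vocabulary-error: trait ", trait, " has no categorical vocabulary",
         call. = FALSE)
  key <- tolower(trimws(token))
  if (!key %in% names(vocab))
    stop("vocabulary-error: unknown token '", token, "' for ", trait,
         call. = FALSE)
  unname(vocab[key])
}

#' Map a taxon-level trait table onto the tips of a tree
#'
#' Transfers observed trait values from named reference taxa to tree tips
#' through a (possibly partial) tip-to-binomial name map; unmatched tips
#' stay missing.
#'
#' @param tree A `phylo` object.
#' @param table A [trait_table()] keyed by taxon names (e.g. Latin
#'   binomials).
#' @param name_map data.frame with columns `tip` and `taxon`.
#' @return A [trait_table()] whose rows are the tree tips, with an
#'   attribute `match_count` (matched tips per trait).
#' @export
map_traits_to_tree <- function(tree, table, name_map) {
  if (anyDuplicated(tree$tip.label))
    stop("invalid-tree: duplicate tip labels", call. = FALSE)
  tips <- tree$tip.label
  vals <- matrix(NA_real_, length(tips), ncol(table$values),
                 dimnames = list(tips, colnames(table$values)))
  if (nrow(name_map)) {
    nm <- name_map[name_map$tip %in% tips & name_map$taxon %in%
                     rownames(table$values), , drop = FALSE]
    vals[nm$tip, ] <- table$values[nm$taxon, , drop = FALSE]
  }
  out <- trait_table(vals, meta = table$meta)
  attr(out, "match_count") <- colSums(!is.na(vals))
  out
}
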