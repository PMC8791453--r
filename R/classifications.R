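#' Variant classification vocabulary
#'
#' Controlled vocabulary for the `variant_classification` field of a
#' variant table, following the MAF convention used by TCGA MC3 and by
#' Oncotator-annotated exomes.
#'
#' @format Character vectors:
#' * `maf_classifications()`: all accepted tokens.
#' * `noncoding_classifications()`: tokens removed by
#'   [exclude_noncoding()] (UTRs, flanks, intronic, RNA genes, de novo
#'   start calls).
#' * `nonsilent_classifications()`: nonsynonymous coding plus splice
#'   junction tokens; these define a "non-silent" mutation.
#' @name classification_vocabulary
NULL

#' @rdname classification_vocabulary
#' @export
maf_classifications <- function() {
  c(nonsilent_classifications(), "Silent", noncoding_classifications())
}

#' @rdname classification_vocabulary
#' @export
noncoding_classifications <- function() {
  c("3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "RNA", "lincRNA",
    "De_novo_Start")
}

#' @rdname classification_vocabulary
#' @export
nonsilent_classifications <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Translation_Start_Site", "Frame_Shift_Ins", "Frame_Shift_Del",
    "In_Frame_Ins", "In_Frame_Del", "Splice_Site")
}

#' Is a classification non-silent?
#'
#' Non-silent mutations are nonsynonymous coding changes plus splice
#' junction changes; `Silent` (synonymous) is not. The input must already
#' be restricted to coding/splice classes (see [exclude_noncoding()]):
#' noncoding tokens are a contract violation, not a `FALSE`.
#'
#' @param classification Character vector of classification tokens.
#' @return Logical vector, `TRUE` where the classification is non-silent.
#' @export
is_nonsilent <- function(classification) {
  bad <- setdiff(unique(classification), c(nonsilent_classifications(), "Silent"))
  if (length(bad) > 0) {
    stop("is_nonsilent() applies to coding/splice classes only; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  classification %in% nonsilent_classifications()
}
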