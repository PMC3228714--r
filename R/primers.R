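#' Construct a primer table
#'
#' Composite amplicon-sequencing primers: a 19-base sequencing adapter
#' followed by a 17-20 base target-specific part (IUPAC ambiguity codes
#' allowed in the target).
#'
#' @param name primer names.
#' @param region amplicon region each primer belongs to.
#' @param adapter 19-base adapter sequences.
#' @param target 17-20 base target-specific sequences.
#' @param orientation `"forward"` (the read 5' end) or `"reverse"`.
#' @return a `data.frame` with one row per primer and a `composite`
#'   column (`adapter` + `target`).
#' @export
primer_table <- function(name, region, adapter, target, orientation) {
  adapter <- toupper(adapter); target <- toupper(target)
  if (any(nchar(adapter) != 19L)) stop("adapters must be 19 bases")
  if (any(nchar(target) < 17L | nchar(target) > 20L))
    stop("primer targets must be 17-20 bases")
  if (!all(orientation %in% c("forward", "reverse")))
    stop("orientation must be 'forward' or 'reverse'")
  vapply(region, check_region, character(1))
  data.frame(name = name, region = region, adapter = adapter,
             target = target, orientation = orientation,
             composite = paste0(adapter, target), stringsAsFactors = FALSE)
}

#' Default broad-range 16S rDNA primer set
#'
#' The two amplicon systems used throughout the package: V1V2
#' (positions 8-361 of the 16S gene) and V6 (positions 784-1061), each as
#' a composite of the platform sequencing adapter (A for the forward read
#' primer, B for the reverse) and the target-specific part.
#'
#' @return a primer table (see [primer_table()]).
#' @export
default_primers <- function() {
  primer_table(
    name = c("A2+V1F", "B2+V2R", "A2+1061R", "B2+784F"),
    region = c("V1V2", "V1V2", "V6", "V6"),
    adapter = c("GCCTCCCTCGCGCCATCAG", "GCCTTGCCAGCCCGCTCAG",
                "GCCTCCCTCGCGCCATCAG", "GCCTTGCCAGCCCGCTCAG"),
    target = c("AGAGTTTGATCMTGGCTCAG", "CYNACTGCTGCCTCCCGTAG",
               "CRRCACGAGCTGACGAC", "AGGATTAGATACCCTGGTA"),
    orientation = c("forward", "reverse", "forward", "reverse"))
}
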