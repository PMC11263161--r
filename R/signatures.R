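# The signature table: one row per piece of SV evidence from one read.

.SIG_COLS <- c("chrom", "left", "right", "length", "sv_type", "read_id",
               "haplotype", "source")

#' Construct a signature table
#'
#' One row per SV evidence item extracted from one read: a reference interval
#' (0-based, half-open), a length in bp, an SV type, the originating read and
#' its haplotype label (0 = untagged, 1/2 = tagged), and the evidence source
#' (`cigar` for intra-read events, `split` for inter-alignment breakpoints).
#'
#' @param chrom,left,right,length,sv_type,read_id,haplotype,source vectors of
#'   equal length (recycled length-1 allowed).
#' @return a data.frame of signatures.
#' @export
sv_signatures <- function(chrom = character(), left = integer(),
                          right = integer(), length = integer(),
                          sv_type = character(), read_id = character(),
                          haplotype = integer(), source = "cigar") {
  df <- data.frame(chrom = as.character(chrom), left = as.numeric(left),
                   right = as.numeric(right), length = as.numeric(length),
                   sv_type = as.character(sv_type),
                   read_id = as.character(read_id),
                   haplotype = as.integer(haplotype),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_signatures(df)
  df
}

#' Validate signature-table invariants
#'
#' Checks the structural invariants every signature must satisfy: known SV
#' type, right >= left, positive length, DEL spans equal to their length,
#' INS anchored at a point, haplotype label in \{0, 1, 2\}.
#'
#' @param sigs signature data.frame.
#' @param min_sv_size optional lower bound on length to enforce.
#' @return `sigs`, invisibly; errors on violation.
#' @export
validate_signatures <- function(sigs, min_sv_size = NULL) {
  stopifnot(is.data.frame(sigs), all(.SIG_COLS %in% names(sigs)))
  if (!nrow(sigs)) return(invisible(sigs))
  if (!all(sigs$sv_type %in% SV_TYPES)) stop("unknown sv_type in signatures")
  if (!all(sigs$right >= sigs$left)) stop("signature with right < left")
  if (!all(sigs$length >= 1)) stop("non-positive signature length")
  del <- sigs$sv_type == "DEL"
  if (!all(sigs$right[del] - sigs$left[del] == sigs$length[del]))
    stop("DEL signature whose span differs from its length")
  ins <- sigs$sv_type == "INS"
  if (!all(sigs$right[ins] == sigs$left[ins]))
    stop("INS signature not anchored at a point")
  if (!all(sigs$haplotype %in% 0:2)) stop("haplotype label outside {0, 1, 2}")
  if (!all(sigs$source %in% c("cigar", "split"))) stop("unknown signature source")
  if (!is.null(min_sv_size) && any(sigs$length < min_sv_size))
    stop("signature shorter than min_sv_size")
  invisible(sigs)
}

.empty_signatures <- function() {
  data.frame(chrom = character(), left = numeric(), right = numeric(),
             length = numeric(), sv_type = character(), read_id = character(),
             haplotype = integer(), source = character(),
             stringsAsFactors = FALSE)
}
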