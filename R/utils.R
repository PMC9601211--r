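#' Pfam accessions of polysaccharide-biosynthesis context domains
#'
#' The seven Pfam families whose presence on a neighbor gene marks an OPX
#' candidate as embedded in a polysaccharide synthesis gene cluster. These
#' are the defaults consumed by [contextFilter()] and [assignPathway()].
#'
#' @return Named character vector of Pfam accessions.
#' @examples
#' contextAccessions()
#' @export
contextAccessions <- function() {
  c(ABC2_membrane  = "PF01061",
    ABC_tran       = "PF00005",
    Polysacc_synt  = "PF01943",
    Polysacc_synt3 = "PF13440",
    Wzt_C          = "PF14524",
    Wzy_C          = "PF04932",
    Wzz            = "PF02706")
}

#' Accessions used to flag beta-barrel partner candidates
#'
#' Placeholder accessions standing for the two custom barrel-family HMMs
#' (an EpsX/ExoB-homolog model and a VpsM-orthology model) whose hits mark
#' a neighbor protein as a beta-barrel candidate. Hit tables produced
#' upstream should label barrel hits with one of these accessions (or the
#' caller supplies its own set).
#'
#' @return Named character vector.
#' @export
barrelAccessions <- function() {
  c(epsx_family_hmm = "EPSX_FAM",
    vpsm_family_hmm = "VPSM_FAM")
}

# accessions voting for each pathway when mapping the closest context gene
.WZX_WZY_ACCS <- c("PF04932", "PF01943", "PF13440")
.ABC_ACCS     <- c("PF00005", "PF01061", "PF14524")
.PCP_ACC      <- "PF02706"

#' Default tyrosine-kinase accession used for PCP-2 typing
#' @return Character scalar (a placeholder BY-kinase family accession,
#'   override via the `kinaseAcc` argument of the callers).
#' @export
kinaseAccession <- function() "PF13614"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL uses the
# current stream untouched.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

# stable data.frame constructor: character columns stay character
.df <- function(...) data.frame(..., stringsAsFactors = FALSE)
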