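#' Define an RNA substrate
#'
#' A substrate is a stretch of non-adenosine "3' UTR" nucleotides followed
#' by a homopolymeric poly(A) tail. Standard substrate names such as
#' `"23-mer-A30"` (23 UTR nt, 30-adenosine tail) or `"A30"` (tail only) can
#' be parsed with [parse_substrate_label()].
#'
#' @param utr_length Number of non-poly(A) nucleotides upstream of the tail.
#' @param tail_length Initial number of adenosines.
#' @param label Free-text label.
#' @return An object of class `"substrate_spec"`.
#' @examples
#' substrate_spec(23, 30)
#' parse_substrate_label("20-mer-A60")
#' @export
substrate_spec <- function(utr_length, tail_length, label = NULL) {
  stopifnot(length(utr_length) == 1L, length(tail_length) == 1L)
  utr_length <- as.integer(utr_length)
  tail_length <- as.integer(tail_length)
  if (is.na(utr_length) || utr_length < 0L) {
    stop("utr_length must be a non-negative integer")
  }
  if (is.na(tail_length) || tail_length < 0L) {
    stop("tail_length must be a non-negative integer")
  }
  if (is.null(label)) {
    label <- if (utr_length > 0L) {
      sprintf("%d-mer-A%d", utr_length, tail_length)
    } else {
      sprintf("A%d", tail_length)
    }
  }
  structure(list(utr_length = utr_length, tail_length = tail_length,
                 label = label),
            class = "substrate_spec")
}

#' @rdname substrate_spec
#' @param label_string A name like `"23-mer-A30"`, `"A30"` or `"20-mer-A60"`.
#' @export
parse_substrate_label <- function(label_string) {
  stopifnot(is.character(label_string), length(label_string) == 1L)
  m <- regmatches(label_string,
                  regexec("^(?:([0-9]+)-mer-)?A([0-9]+)$", label_string))[[1]]
  if (length(m) == 0L) {
    stop("cannot parse substrate label: ", label_string)
  }
  utr <- if (m[2] == "") 0L else as.integer(m[2])
  substrate_spec(utr, as.integer(m[3]), label = label_string)
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf("substrate %s: %d nt UTR + A%d tail\n",
              x$label, x$utr_length, x$tail_length))
  invisible(x)
}

#' Define a Pab1 variant
#'
#' Pab1 has four RNA-recognition motifs (RRMs); point mutations can disable
#' RNA binding of individual RRMs. The proline-rich linker plus C-terminal
#' domain (the C-terminal region) mediates the interaction with Ccr4 and is
#' required for rate stimulation; `has_c_terminal_region = FALSE` models the
#' truncation lacking the P-linker and CTD.
#'
#' @param rrm_functional Logical vector of length 4: RRMs 1-4 able to bind.
#' @param has_c_terminal_region Logical; C-terminal region present.
#' @return An object of class `"pab1_variant"`.
#' @examples
#' pab1_wt()
#' pab1_rrm_mutant(4)
#' @export
pab1_variant <- function(rrm_functional = rep(TRUE, 4),
                         has_c_terminal_region = TRUE) {
  if (!is.logical(rrm_functional) || length(rrm_functional) != 4L ||
      anyNA(rrm_functional)) {
    stop("rrm_functional must be 4 non-missing logical flags")
  }
  structure(list(rrm_functional = rrm_functional,
                 has_c_terminal_region = isTRUE(has_c_terminal_region)),
            class = "pab1_variant")
}

#' @rdname pab1_variant
#' @export
pab1_wt <- function() pab1_variant()

#' @rdname pab1_variant
#' @param which_rrm RRM index (1-4) whose RNA binding is impaired.
#' @export
pab1_rrm_mutant <- function(which_rrm) {
  stopifnot(which_rrm %in% 1:4)
  flags <- rep(TRUE, 4)
  flags[which_rrm] <- FALSE
  pab1_variant(flags)
}

#' @export
print.pab1_variant <- function(x, ...) {
  bad <- which(!x$rrm_functional)
  cat("Pab1 variant: ",
      if (length(bad)) paste0("RRM", bad, "mut", collapse = "+") else "WT",
      if (!x$has_c_terminal_region) ", no C-terminal region" else "",
      "\n", sep = "")
  invisible(x)
}

# Footprint geometry for one bound molecule, looked up from the geometry
# table by binding mode and the set of RRMs engaged *on the tail*.
# utr_anchored: RRM4 occupies the UTR, RRMs 1-3 (those functional) engage
# the tail. all_polyA: all functional RRMs engage the tail. Pause edges are
# the 3' footprint edges of engaged RRMs; the hard stop (smallest tail a
# Caf1-class activity reaches) belongs to the 5'-most engaged RRM.
footprint_geometry <- function(binding_mode, variant, config) {
  geo <- config$geometry[[binding_mode]]
  if (is.null(geo)) stop("unknown binding mode: ", binding_mode)
  on_tail <- if (binding_mode == "utr_anchored") 1:3 else 1:4
  engaged <- on_tail[variant$rrm_functional[on_tail]]
  edges <- unlist(geo$pause_edges)[paste0("rrm", engaged)]
  stops <- unlist(geo$hard_stops)
  pause_sites <- sort(unname(edges))
  hard_stop <- if (length(engaged)) {
    unname(stops[paste0("rrm", max(engaged))])
  } else 0L
  # RRM1/RRM2 mutants blur the remaining steps (heuristic, see vignette)
  dwell_factor <- if (!all(variant$rrm_functional[1:2])) {
    config$geometry$mutant_dwell_factor
  } else 1
  span <- hard_stop  # engaged adenosines when the full footprint is covered
  structure(list(binding_mode = binding_mode,
                 pause_sites = as.integer(pause_sites),
                 hard_stop = as.integer(hard_stop),
                 span = as.integer(span),
                 release_threshold = as.integer(geo$release_threshold),
                 dwell_factor = dwell_factor),
            class = "footprint_geometry")
}

#' Maximum Pab1 loading of a substrate
#'
#' Loading capacity follows the measured stoichiometries: the proximal
#' (UTR-anchored) molecule accounts for `proximal_span` tail adenosines and
#' each additional molecule needs a further `distal_span`. A60-class tails
#' therefore take two molecules, A30- and A10-class tails one, and a
#' tail-less substrate none.
#'
#' @param substrate A [substrate_spec()].
#' @param variant A [pab1_variant()].
#' @param config A [load_config()] result; default shipped config.
#' @return Integer capacity.
#' @examples
#' max_loading(parse_substrate_label("20-mer-A60"), pab1_wt())  # 2
#' max_loading(parse_substrate_label("23-mer-A30"), pab1_wt())  # 1
#' @export
max_loading <- function(substrate, variant = pab1_wt(),
                        config = default_config()) {
  stopifnot(inherits(substrate, "substrate_spec"))
  cap <- config$geometry$capacity
  tl <- substrate$tail_length
  if (tl == 0L) return(0L)
  as.integer(1L + max(0L, (tl - cap$proximal_span) %/% cap$distal_span))
}

#' Assemble a Pab1-loaded mRNP
#'
#' Places `n_pab1` molecules 5' to 3' on the tail. The 5'-most molecule is
#' UTR-anchored (RRM4 on the UTR, RRMs 1-3 on poly(A)) when the substrate
#' has a UTR and RRM4 is functional; otherwise, and for all distal
#' molecules, binding is in all-poly(A) mode. Each molecule's footprint
#' geometry is looked up from the configured geometry table.
#'
#' @inheritParams max_loading
#' @param n_pab1 Number of Pab1 molecules to load.
#' @return An object of class `"mrnp_state"`.
#' @examples
#' assemble_mrnp(parse_substrate_label("23-mer-A30"), pab1_wt(), 1)
#' @export
assemble_mrnp <- function(substrate, variant = pab1_wt(), n_pab1 = 1,
                          config = default_config()) {
  stopifnot(inherits(substrate, "substrate_spec"),
            inherits(variant, "pab1_variant"))
  n_pab1 <- as.integer(n_pab1)
  capacity <- max_loading(substrate, variant, config)
  if (n_pab1 > capacity) {
    stop(sprintf(
      "cannot load %d Pab1 molecules on substrate %s (capacity %d)",
      n_pab1, substrate$label, capacity))
  }
  bound <- vector("list", n_pab1)
  offset <- 1L
  for (i in seq_len(n_pab1)) {
    mode <- if (i == 1L && substrate$utr_length > 0L &&
                variant$rrm_functional[4]) "utr_anchored" else "all_polyA"
    geom <- footprint_geometry(mode, variant, config)
    bound[[i]] <- structure(list(variant = variant,
                                 binding_mode = mode,
                                 five_prime_offset = offset,
                                 geometry = geom),
                            class = "bound_pab1")
    offset <- offset + geom$span
  }
  structure(list(substrate = substrate,
                 tail_remaining = substrate$tail_length,
                 bound = bound,
                 released_count = 0L),
            class = "mrnp_state")
}

#' @export
print.mrnp_state <- function(x, ...) {
  cat(sprintf("mRNP on %s: tail %d/%d nt, %d Pab1 bound (%d released)\n",
              x$substrate$label, x$tail_remaining,
              x$substrate$tail_length, length(x$bound), x$released_count))
  for (b in x$bound) {
    cat(sprintf("  Pab1 at tail position %d, %s, footprint %d nt\n",
                b$five_prime_offset, b$binding_mode, b$geometry$span))
  }
  invisible(x)
}

# absolute protected boundary: highest tail position shielded from a
# Caf1-class activity (0 when nothing protects)
protected_boundary <- function(state) {
  if (!length(state$bound)) return(0L)
  b <- state$bound[[length(state$bound)]]   # 3'-most molecule
  b$five_prime_offset - 1L + b$geometry$hard_stop
}

#' Smallest tail length reachable by an enzyme configuration
#'
#' An enzyme with a nonzero engaged-region rate eventually removes the full
#' tail; an engaged-rate-zero (Caf1-class) activity stalls at the hard stop
#' of the 3'-most bound molecule, i.e. its offset plus its mode's hard-stop
#' length, which stacks the full footprints of any 5'-ward molecules.
#'
#' @param state An [assemble_mrnp()] state.
#' @param enzyme An [enzyme_ruleset()].
#' @return Tail length in nt.
#' @examples
#' st <- assemble_mrnp(parse_substrate_label("23-mer-A30"), pab1_wt(), 1)
#' protected_limit(st, enzyme_ruleset("ccr4not_ccr4_inactive"))  # 22
#' protected_limit(st, enzyme_ruleset("ccr4not_wt"))             # 0
#' @export
protected_limit <- function(state, enzyme) {
  stopifnot(inherits(state, "mrnp_state"), inherits(enzyme, "enzyme_ruleset"))
  if (enzyme$k_naked == 0 && enzyme$k_engaged == 0) {
    return(state$tail_remaining)
  }
  if (enzyme$k_engaged > 0 || !length(state$bound)) return(0L)
  as.integer(min(state$tail_remaining, protected_boundary(state)))
}

#' Pause sites of a Pab1-loaded state
#'
#' Union of the bound molecules' pause sites (3' RRM footprint edges),
#' shifted by each molecule's tail offset, sorted ascending. Deadenylation
#' by the intact complex dwells at each of these tail lengths, producing
#' the regularly spaced gel bands.
#'
#' @param state An [assemble_mrnp()] state.
#' @return Integer vector of tail lengths (possibly empty).
#' @examples
#' pause_sites(assemble_mrnp(parse_substrate_label("23-mer-A30")))  # 8 16 24
#' @export
pause_sites <- function(state) {
  stopifnot(inherits(state, "mrnp_state"))
  if (!length(state$bound)) return(integer(0))
  sites <- unlist(lapply(state$bound, function(b) {
    b$five_prime_offset - 1L + b$geometry$pause_sites
  }))
  sort(unique(as.integer(sites)))
}
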