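#' Electrode montage layout
#'
#' Describes the implanted contact geometry and the bipolar derivation built
#' from it. The default layout mirrors a two-assembly device: 2 lead
#' assemblies x 2 electrode arrays per assembly x 4 contacts per array
#' (16 contacts). Bipolar channels are differences of consecutive contacts
#' within each array, giving 3 pairs per array and 12 bipolar pairs in total
#' for the default layout.
#'
#' @param assemblies number of lead assemblies.
#' @param arrays_per_assembly electrode arrays per assembly.
#' @param contacts_per_array contacts per array.
#' @return An object of class `montage_layout`: a list with the geometry and a
#'   `pairs` matrix (one row per bipolar channel, columns `i`, `j` giving the
#'   contact indices that are subtracted).
#' @examples
#' layout <- montage_layout()
#' nrow(layout$pairs)  # 12
#' @export
montage_layout <- function(assemblies = 2L, arrays_per_assembly = 2L,
                           contacts_per_array = 4L) {
  assemblies <- as.integer(assemblies)
  arrays_per_assembly <- as.integer(arrays_per_assembly)
  contacts_per_array <- as.integer(contacts_per_array)
  if (assemblies < 1L || arrays_per_assembly < 1L || contacts_per_array < 2L)
    stop("montage_layout: need >= 1 assembly/array and >= 2 contacts per array")
  n_arrays <- assemblies * arrays_per_assembly
  n_contacts <- n_arrays * contacts_per_array
  pairs <- do.call(rbind, lapply(seq_len(n_arrays), function(a) {
    base <- (a - 1L) * contacts_per_array
    cbind(i = base + seq_len(contacts_per_array - 1L),
          j = base + seq_len(contacts_per_array - 1L) + 1L)
  }))
  structure(
    list(assemblies = assemblies,
         arrays_per_assembly = arrays_per_assembly,
         contacts_per_array = contacts_per_array,
         n_contacts = n_contacts,
         pairs = pairs),
    class = "montage_layout"
  )
}

#' Apply a bipolar montage
#'
#' Re-references raw contact signals by taking differences between consecutive
#' contacts within each array, suppressing artifacts common across channels.
#'
#' @param raw numeric matrix, contacts x samples.
#' @param layout a [montage_layout()].
#' @return numeric matrix, bipolar channels x samples; row `k` equals
#'   `raw[i_k, ] - raw[j_k, ]` for the k-th consecutive contact pair.
#' @examples
#' raw <- matrix(rnorm(16 * 100), nrow = 16)
#' bp <- make_bipolar(raw, montage_layout())
#' dim(bp)  # 12 x 100
#' @export
make_bipolar <- function(raw, layout = montage_layout()) {
  if (!inherits(layout, "montage_layout")) stop("layout must be a montage_layout")
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("raw must be a numeric matrix (contacts x samples)")
  if (nrow(raw) != layout$n_contacts)
    stop(sprintf("contact count mismatch: layout expects %d contacts, got %d rows",
                 layout$n_contacts, nrow(raw)))
  out <- raw[layout$pairs[, "i"], , drop = FALSE] -
    raw[layout$pairs[, "j"], , drop = FALSE]
  rownames(out) <- paste0("bp", seq_len(nrow(out)))
  out
}
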