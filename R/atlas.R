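# Destrieux-style cortical labels, 74 per hemisphere (gyri "G_", sulci "S_").
.destrieux74 <- c(
  "G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
  "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
  "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
  "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
  "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
  "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
  "G_insular_short", "G_occipital_middle", "G_occipital_sup",
  "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip",
  "G_orbital", "G_pariet_inf-Angular", "G_pariet_inf-Supramar",
  "G_parietal_sup", "G_postcentral", "G_precentral", "G_precuneus",
  "G_rectus", "G_subcallosal", "G_temp_sup-G_T_transv",
  "G_temp_sup-Lateral", "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo",
  "G_temporal_inf", "G_temporal_middle", "Lat_Fis-ant-Horizont",
  "Lat_Fis-ant-Vertical", "Lat_Fis-post", "Pole_occipital",
  "Pole_temporal", "S_calcarine", "S_central", "S_cingul-Marginalis",
  "S_circular_insula_ant", "S_circular_insula_inf",
  "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
  "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
  "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
  "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
  "S_oc-temp_med_and_Lingual", "S_orbital_lateral", "S_orbital_med-olfact",
  "S_orbital-H_Shaped", "S_parieto_occipital", "S_pericallosal",
  "S_postcentral", "S_precentral-inf-part", "S_precentral-sup-part",
  "S_suborbital", "S_subparietal", "S_temporal_inf", "S_temporal_sup",
  "S_temporal_transverse")

#' Default 165-parcel atlas
#'
#' Builds the package's default parcel atlas: 74 Destrieux-style cortical
#' labels per hemisphere (`lh.`/`rh.` prefixes), the brain stem, and 16
#' unassigned midline filler labels, for 165 parcels in total. The cortical
#' label set is the standard surface-parcellation vocabulary, so region-wise
#' result tables read like the usual atlas exports; the midline fillers make
#' the parcel count match the 165-response dimensionality used throughout
#' and are plain placeholders.
#'
#' @return a [ParcelAtlas] of length 165.
#' @examples
#' atl <- defaultAtlas()
#' head(parcelLabels(atl))
#' @export
defaultAtlas <- function() {
  labels <- c(paste0("lh.", .destrieux74), paste0("rh.", .destrieux74),
              "mid.Brain-stem",
              sprintf("mid.Unassigned_%02d", seq_len(16)))
  ParcelAtlas(labels = labels, hemisphere = .hemiFromLabel(labels))
}

#' Bilateral region labels carrying the planted interaction by default
#'
#' The 11 temporal/parietal regions (both hemispheres, 22 parcels) in which
#' the synthetic generator plants the sex-by-diagnosis interaction on
#' connectivity density: lateral temporal cortex, the
#' temporo-parieto-occipital junction and the medial parietal lobe.
#'
#' @return character vector of 22 parcel labels, all present in
#'   [defaultAtlas()].
#' @export
defaultTargetParcels <- function() {
  base <- c("G_pariet_inf-Angular", "S_parieto_occipital",
            "G_temporal_middle", "G_pariet_inf-Supramar", "G_cuneus",
            "G_temp_sup-Lateral", "S_interm_prim-Jensen", "S_temporal_sup",
            "G_insular_short", "G_precuneus", "G_temp_sup-Plan_polar")
  c(paste0("lh.", base), paste0("rh.", base))
}

#' Read / write a parcel atlas file
#'
#' Plain-text atlas format: one parcel label per line, `lh.`/`rh.`/`mid.`
#' prefix convention, order significant.
#'
#' @param path file path.
#' @param atlas a [ParcelAtlas].
#' @return `readParcelAtlas()` a [ParcelAtlas]; `writeParcelAtlas()` the
#'   path, invisibly.
#' @export
readParcelAtlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  labels <- readLines(path)
  labels <- labels[nzchar(trimws(labels))]
  ParcelAtlas(labels = labels, hemisphere = .hemiFromLabel(labels))
}

#' @rdname readParcelAtlas
#' @export
writeParcelAtlas <- function(atlas, path) {
  writeLines(parcelLabels(atlas), path)
  invisible(path)
}
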