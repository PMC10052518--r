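# Shared fixtures, computed lazily once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

ref_fixture <- function() fixture("reference", make_reference_complex)

catalog_fixture <- function() {
  fixture("catalog", function() default_catalog(ref_fixture()))
}

# standard planted-geometry toy: 3 H-bonds, 1 salt bridge, 1 CA contact,
# 1 hydrophilic pair, 1 B2M contact pair
toy_fixture <- function() {
  fixture("toy", function()
    make_toy_complex(hbonds = c(2.8, 3.0, 3.2), salt_bridges = 3.7,
                     ca_contacts = 3.8, hydrophilic = 3.7,
                     b2m_contacts = 3.8, n_fc = 8, n_fcrn = 6, n_b2m = 2))
}

# the full synthetic study dataset (n = 500, sigma = 0.15, seed 1)
gen_fixture <- function() {
  fixture("gen500", function()
    make_variant_table(synthetic_truth(n = 500L, sigma = 0.15, seed = 1L),
                       reference = ref_fixture(),
                       catalog = catalog_fixture()))
}

# minimal hand-built complex for targeted geometry cases
tiny_complex <- function(atoms) {
  atoms$radius <- vdw_radius(atoms$element)
  structure(list(atoms = atoms,
                 chain_map = c(FC = "A", FCRN_ALPHA = "B"),
                 source_id = "tiny"),
            class = "fc_complex")
}

tiny_atom <- function(role, chain, eu, aa, elety, x, y, z) {
  data.frame(role = role, chain = chain, resno = eu, eu = eu, aa = aa,
             elety = elety, element = substr(elety, 1, 1),
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}
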