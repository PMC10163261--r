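# Default elastic constants and force-free domain contour lengths.
# Lengths in nm, moduli in pN, temperature in kelvin.
l_c_nm: 0.4          # contour length per unfolded amino acid
l_p_nm: 0.36         # persistence length of unfolded polypeptide
E_p_pN: 1000         # stretch modulus, unfolded polypeptide
E_c_pN: 1000         # stretch modulus, folded globular domains
kuhn_nm: 3.0         # shared Kuhn segment length of the semi-rigid bodies
temperature_K: 297.7 # room temperature; kBT = 4.11 pN nm
domain_lengths_nm:
  "N": 15.0            # whole receptor-ligand ectodomain span, bound state
  alpha3: 4.0        # dissociated MHC-I alpha3 end-to-end span (default)
  BI: 6.0            # bonding interface: MHC platform + TCR variable domains
  Calphabeta: 3.0    # TCR Calpha-Cbeta module
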