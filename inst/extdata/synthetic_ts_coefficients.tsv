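# SYNTHETIC temperature/salinity correction coefficient table.
# Shapes are plausible for a hyperspectral absorption/attenuation meter
# but these are NOT published literature coefficients; supply a real
# instrument table for real data.
# t_r: 19.0
wavelength	psi_t	psi_sa	psi_sc
390	2e-04	-1.5e-05	-2.699e-05
400	2e-04	-1.514e-05	-2.674e-05
410	2e-04	-1.528e-05	-2.646e-05
420	2e-04	-1.542e-05	-2.614e-05
430	2e-04	-1.556e-05	-2.579e-05
440	2e-04	-1.569e-05	-2.541e-05
450	2e-04	-1.583e-05	-2.5e-05
460	2e-04	-1.597e-05	-2.458e-05
470	2e-04	-1.611e-05	-2.415e-05
480	2e-04	-1.625e-05	-2.373e-05
490	2e-04	-1.639e-05	-2.333e-05
500	2e-04	-1.653e-05	-2.296e-05
510	2e-04	-1.667e-05	-2.263e-05
520	2e-04	-1.681e-05	-2.236e-05
530	2e-04	-1.694e-05	-2.216e-05
540	2e-04	-1.708e-05	-2.204e-05
550	2e-04	-1.722e-05	-2.2e-05
560	2e-04	-1.736e-05	-2.204e-05
570	2e-04	-1.75e-05	-2.216e-05
580	2e-04	-1.764e-05	-2.236e-05
590	2e-04	-1.778e-05	-2.263e-05
600	2e-04	-1.792e-05	-2.296e-05
610	2e-04	-1.806e-05	-2.333e-05
620	2e-04	-1.819e-05	-2.373e-05
630	2e-04	-1.833e-05	-2.415e-05
640	2e-04	-1.847e-05	-2.458e-05
650	0.0002004	-1.861e-05	-2.5e-05
660	0.0002024	-1.875e-05	-2.541e-05
670	0.000213	-1.889e-05	-2.579e-05
680	0.0002549	-1.903e-05	-2.614e-05
690	0.0003865	-1.917e-05	-2.646e-05
700	0.000707	-1.931e-05	-2.674e-05
710	0.0013036	-1.944e-05	-2.699e-05
720	0.0021235	-1.958e-05	-2.719e-05
730	0.0028845	-1.972e-05	-2.737e-05
740	0.0032	-1.986e-05	-2.751e-05
750	0.0028845	-2e-05	-2.763e-05
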