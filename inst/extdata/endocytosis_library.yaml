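# Declarative library of kinetic functional-form alternatives for the
# two-protein (Rab5/Rab7) conversion-switch template.
#
# Each regulatory slot lists its mutually exclusive alternatives; an
# alternative is one or two rate-law components. Component kinds:
#   intrinsic            rate = k                      (non-catalyzed)
#   michaelis_menten     rate = V * X / (Km + X)
#   sigmoidal            rate = V * X^h / (Km^h + X^h) (h fixed, see below)
#   exchange_inhibition  rate = V * Km / (Km + X)      (X inhibits)
#   linear               rate = k * X
# X is the active-state concentration of the named regulator.
#
# Slot sizes 3 x 3 x 7 x 2 give the 126-structure candidate space.
hill_exponent: 3
bounds:
  kinetic: [0.001, 4.0]     # all rate constants V, k and half-saturations Km (1/s or conc.)
  initial: [0.0, 2.0]       # initial concentrations r5_0, R5_0, r7_0, R7_0
  scaling: [1.0e+3, 1.0e+5] # observation scaling factor K (intensity per concentration)
  onset:   [5.0, 195.0]     # onset offset td (s)
slots:
  gef5:
    - name: mm_auto
      components:
        - {role: main, kind: michaelis_menten, regulator: R5}
    - name: sigmoidal_auto
      components:
        - {role: main, kind: sigmoidal, regulator: R5}
    - name: exchange_inhibition_by_r7
      components:
        - {role: main, kind: exchange_inhibition, regulator: R7}
  gap5:
    - name: intrinsic
      components:
        - {role: main, kind: intrinsic, regulator: none}
    - name: mm_by_r7
      components:
        - {role: main, kind: michaelis_menten, regulator: R7}
    - name: sigmoidal_by_r7
      components:
        - {role: main, kind: sigmoidal, regulator: R7}
  gef7:
    - name: mm_cross
      components:
        - {role: cross, kind: michaelis_menten, regulator: R5}
    - name: mm_cross_mm_auto
      components:
        - {role: cross, kind: michaelis_menten, regulator: R5}
        - {role: auto, kind: michaelis_menten, regulator: R7}
    - name: mm_cross_sigmoidal_auto
      components:
        - {role: cross, kind: michaelis_menten, regulator: R5}
        - {role: auto, kind: sigmoidal, regulator: R7}
    - name: sigmoidal_cross
      components:
        - {role: cross, kind: sigmoidal, regulator: R5}
    - name: sigmoidal_cross_mm_auto
      components:
        - {role: cross, kind: sigmoidal, regulator: R5}
        - {role: auto, kind: michaelis_menten, regulator: R7}
    - name: sigmoidal_cross_sigmoidal_auto
      components:
        - {role: cross, kind: sigmoidal, regulator: R5}
        - {role: auto, kind: sigmoidal, regulator: R7}
    - name: linear_cross
      components:
        - {role: cross, kind: linear, regulator: R5}
  gap7:
    - name: intrinsic
      components:
        - {role: main, kind: intrinsic, regulator: none}
    - name: mm_by_r5
      components:
        - {role: main, kind: michaelis_menten, regulator: R5}
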