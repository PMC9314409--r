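- site_id: gHR1a
  protospacer: GTCGGTCCCACGATATTTGA
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12815
  fork_direction: rightward
- site_id: gHR1b
  protospacer: TGCCTCTTCAACACAGATAT
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12838
  fork_direction: rightward
- site_id: gHR2
  protospacer: AACACAGATATAGGGATAAC
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12847
  fork_direction: rightward
- site_id: gHR3
  protospacer: CCATTTGATCGCTGTTATCG
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12877
  fork_direction: rightward
- site_id: gEmx7
  protospacer: GTCGGTCCCACGATATTTGA
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12815
  fork_direction: rightward
- site_id: gEmx8
  protospacer: TCCCTATATCTGTGTTGAAG
  pam_strand: Crick
  nickase: Cas9
  cut_pos: 12829
  fork_direction: rightward
- site_id: gEmx9
  protospacer: TGCCTCTTCAACACAGATAT
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12838
  fork_direction: rightward
- site_id: gEmx10
  protospacer: CCGCGATAACAGCGATCAAA
  pam_strand: Crick
  nickase: Cas9
  cut_pos: 12866
  fork_direction: rightward
- site_id: gEmx11
  protospacer: CCGCGATAACAGCGATCAAA
  pam_strand: Crick
  nickase: Cas9
  cut_pos: 12866
  fork_direction: rightward
- site_id: gEmx12
  protospacer: AACACAGATATAGGGATAAC
  pam_strand: Watson
  nickase: Cas9
  cut_pos: 12847
  fork_direction: rightward
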